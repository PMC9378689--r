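test_that("paused fraction handles endpoints and cytosine calibration", {
  expect_equal(paused_fraction(0, 100, 10, 20), 0)
  expect_equal(paused_fraction(100, 0, 10, 20), 1)
  # equal molar amounts after calibration: 50/10C vs 100/20C
  expect_equal(paused_fraction(50, 100, 10, 20), 0.5)
  expect_error(paused_fraction(0, 0, 10, 20), "zero")
  expect_error(paused_fraction(-1, 5, 10, 20), ">= 0")
})

test_that("paused fraction is exposure-invariant", {
  for (k in c(0.1, 1, 7, 300)) {
    expect_equal(paused_fraction(k * 30, k * 80, 17, 37),
                 paused_fraction(30, 80, 17, 37))
  }
})

test_that("relative anti-pausing activity is the linear WT/put- scale", {
  expect_equal(relative_anti_pausing(0.15, 0.15, 0.6), 1)
  expect_equal(relative_anti_pausing(0.6, 0.15, 0.6), 0)
  expect_equal(relative_anti_pausing(0.375, 0.15, 0.6), 0.5)
  expect_error(relative_anti_pausing(0.3, 0.4, 0.4), "undefined")
})

test_that("activity is invariant under affine rescaling of all P values", {
  set.seed(5)
  for (k in 1:10) {
    p <- sort(runif(3))
    a <- runif(1, 0.5, 2); b <- runif(1, -0.1, 0.1)
    expect_equal(relative_anti_pausing(p[2], p[1], p[3]),
                 relative_anti_pausing(a * p[2] + b, a * p[1] + b,
                                       a * p[3] + b))
  }
})

test_that("mutants are classified by the 0.2 / 0.9 thresholds with SEM", {
  mk_lanes <- function(label, acts) do.call(rbind, lapply(seq_along(acts),
    function(i) data.frame(label = label, replicate = i,
                           paused_intensity = 100 * (0.15 + (1 - acts[i]) * 0.45),
                           runoff_intensity = 100 * (1 - (0.15 + (1 - acts[i]) * 0.45)),
                           n_c_paused = 1L, n_c_runoff = 1L)))
  lanes <- rbind(mk_lanes("WT", c(1, 1, 1)), mk_lanes("put-", c(0, 0, 0)),
                 mk_lanes("inact", c(0.05, 0.10, 0.15)),
                 mk_lanes("inert1", c(0.95, 0.92, 0.98)),
                 mk_lanes("mid", c(0.5, 0.6, 0.55)))
  res <- classify_mutants(lanes)
  get <- function(lb, col) res[[col]][res$label == lb]
  expect_equal(get("inact", "mean_activity"), 0.10, tolerance = 1e-9)
  expect_equal(get("inact", "class"), "inactivating")
  expect_equal(get("inert1", "class"), "inert")
  expect_equal(get("mid", "class"), "other")
  expect_equal(get("inact", "sem"), sd(c(0.05, 0.10, 0.15)) / sqrt(3),
               tolerance = 1e-9)
  expect_equal(get("WT", "mean_activity"), 1)
  expect_equal(get("put-", "mean_activity"), 0)
})

test_that("a single replicate yields NA SEM but still a class", {
  lanes <- data.frame(label = c("WT", "put-", "m"), replicate = 1L,
                      paused_intensity = c(15, 60, 37.5),
                      runoff_intensity = c(85, 40, 62.5),
                      n_c_paused = 1L, n_c_runoff = 1L)
  res <- classify_mutants(lanes)
  expect_true(is.na(res$sem[res$label == "m"]))
  expect_equal(res$class[res$label == "m"], "other")
})

test_that("noiseless synthetic gels invert exactly; noisy ones within 0.05", {
  truth <- c(m00 = 0, m25 = 0.25, m50 = 0.5, m75 = 0.75, m100 = 1)
  exact <- make_gel_dataset(truth, noise_cv = 0, seed = 10L)
  res <- classify_mutants(exact$lanes)
  for (lb in names(truth))
    expect_equal(res$mean_activity[res$label == lb], truth[[lb]],
                 tolerance = 1e-9)
  expect_equal(res$mean_activity[res$label == "WT"], 1, tolerance = 1e-12)
  expect_equal(res$mean_activity[res$label == "put-"], 0, tolerance = 1e-12)

  noisy <- make_gel_dataset(truth, noise_cv = 0.05, n_replicates = 3L,
                            seed = 11L)
  resn <- classify_mutants(noisy$lanes)
  err <- vapply(names(truth), function(lb)
    abs(resn$mean_activity[resn$label == lb] - truth[[lb]]), 0)
  expect_lt(mean(err), 0.05)
  # ground-truth 0.6 activity at 5% noise recovers within 0.05 and stays
  # in the middle class
  g6 <- make_gel_dataset(c(mut = 0.6), noise_cv = 0.05, seed = 12L)
  r6 <- classify_mutants(g6$lanes)
  expect_lt(abs(r6$mean_activity[r6$label == "mut"] - 0.6), 0.05)
  expect_equal(r6$class[r6$label == "mut"], "other")
})

test_that("conservation scores count identity to the reference", {
  aln <- c(ref = "AGACG", s1 = "AGACG", s2 = "AGACG", s3 = "AGACG",
           s4 = "AGACG", s5 = "AGUCG", s6 = "AAUCG", s7 = "CGACG",
           s8 = "AGACC", s9 = "AGACG")
  p <- conservation_profile(aln, "ref")
  expect_equal(unname(p$scores), c(9, 9, 8, 10, 9))
  # all-identical alignment scores N everywhere
  same <- setNames(rep("ACGU", 10), paste0("q", 1:10))
  p10 <- conservation_profile(same, "q1")
  expect_true(all(p10$scores == 10))
  # reference alone scores 1; gaps never match
  p1 <- conservation_profile(c(only = "AC-GU"), "only")
  expect_true(all(p1$scores == 1))
  expect_equal(length(p1$scores), 4L)
  expect_equal(unname(p1$column_map), c(1L, 2L, 4L, 5L))
  expect_error(conservation_profile(aln, "nope"), "absent")
})

test_that("alignments read from FASTA and Clustal files give the same profile", {
  aln <- c(ref = "AGACGU", s1 = "AG-CGU", s2 = "AGACGA")
  fa <- withr::local_tempfile(fileext = ".fasta")
  writeLines(paste0(">", names(aln), "\n", aln), fa)
  p_fa <- conservation_profile(fa, "ref")
  p_mem <- conservation_profile(aln, "ref")
  expect_equal(p_fa$scores, p_mem$scores)
  cl <- withr::local_tempfile(fileext = ".aln")
  writeLines(c("CLUSTAL W (putkit test)", "", "",
               sprintf("%-6s %s", names(aln), aln)), cl)
  p_cl <- conservation_profile(cl, "ref", format = "clustal")
  expect_equal(p_cl$scores, p_mem$scores)
  st <- withr::local_tempfile(fileext = ".sto")
  writeLines(c("# STOCKHOLM 1.0", sprintf("%s %s", names(aln), aln), "//"),
             st)
  p_st <- conservation_profile(st, "ref", format = "stockholm")
  expect_equal(p_st$scores, p_mem$scores)
})
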