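test_that("chain masses are additive with one water per join", {
  w <- putkit:::water_mass("average")
  set.seed(3)
  for (k in 1:5) {
    n <- sample(4:30, 1)
    s <- paste(sample(c("A", "C", "G", "U"), n, replace = TRUE),
               collapse = "")
    cut <- sample(seq_len(n - 1L), 1)
    s1 <- substr(s, 1, cut); s2 <- substr(s, cut + 1, n)
    expect_equal(rna_mass(s, "monophosphate"),
                 rna_mass(s1, "monophosphate") +
                   rna_mass(s2, "monophosphate") - w,
                 tolerance = 1e-9)
  }
})

test_that("single-nucleotide masses match an independent formula oracle", {
  # oracle: nucleoside-5'-monophosphate molecular formulas, IUPAC 2021
  # average atomic weights, minus one water for the chain residue
  aw <- c(C = 12.011, H = 1.008, N = 14.007, O = 15.999, P = 30.973762)
  nmp <- list(A = c(C = 10, H = 14, N = 5, O = 7, P = 1),   # AMP
              C = c(C = 9, H = 14, N = 3, O = 8, P = 1),    # CMP
              G = c(C = 10, H = 14, N = 5, O = 8, P = 1),   # GMP
              U = c(C = 9, H = 13, N = 2, O = 9, P = 1))    # UMP
  water <- 2 * aw[["H"]] + aw[["O"]]
  for (b in names(nmp)) {
    oracle <- sum(aw[names(nmp[[b]])] * nmp[[b]])
    expect_equal(rna_mass(b, five_prime = "monophosphate"), oracle,
                 tolerance = 0.01)
    expect_equal(rna_residue_mass(b), oracle - water, tolerance = 0.01)
  }
})

test_that("appending uridine adds exactly the uridine residue mass", {
  s94 <- paste(rep_len(c("A", "C", "G", "U"), 94), collapse = "")
  s95 <- paste0(s94, "U")
  expect_equal(rna_mass(s95) - rna_mass(s94), rna_residue_mass("U"),
               tolerance = 1e-9)
  # strictly increasing under appending any nucleotide
  for (b in c("A", "C", "G", "U"))
    expect_gt(rna_mass(paste0(s94, b)), rna_mass(s94))
})

test_that("terminal chemistry shifts the mass by phosphate increments", {
  s <- "ACGU"
  hpo3 <- putkit:::hpo3_mass("average")
  expect_equal(rna_mass(s, "triphosphate") - rna_mass(s, "monophosphate"),
               2 * hpo3, tolerance = 1e-9)
  expect_equal(rna_mass(s, "monophosphate") - rna_mass(s, "hydroxyl"),
               hpo3, tolerance = 1e-9)
  expect_error(rna_mass("ACGT"), "position 4")
  expect_error(rna_mass(""), "empty")
})

test_that("simulated charge series are monotone and closed-form at z = 1", {
  ps <- simulate_charge_series(1000, c(1, 1))
  expect_equal(ps$mz, 1000 + 1.00728)
  ps2 <- simulate_charge_series(30936, c(8, 15))
  expect_equal(nrow(ps2), 8L)
  expect_false(is.unsorted(ps2$mz))
  expect_true(all(diff(ps2$charge) < 0))      # z falls as m/z grows
})

test_that("simulate -> deconvolve is the identity to 1e-6 Da", {
  for (M in c(10000, 30936, 40000)) {
    ps <- simulate_charge_series(M, c(8, 15))
    dv <- deconvolve_charge_series(ps, z_search = c(1, 40), tolerance = 5)
    expect_equal(dv$neutral_mass, M, tolerance = 1e-6)
    expect_lt(dv$residual, 1e-6)
    expect_equal(dv$charge_assignments$charge, 15:8)
  }
})

test_that("deconvolution tolerates m/z jitter and ignores intensity scale", {
  set.seed(21)
  ps <- simulate_charge_series(30936, c(9, 14))
  ps$mz <- ps$mz + rnorm(nrow(ps), sd = 0.05)
  dv <- deconvolve_charge_series(ps, z_search = c(1, 40), tolerance = 5)
  expect_lt(abs(dv$neutral_mass - 30936), 2)
  ps_scaled <- ps
  ps_scaled$intensity <- ps$intensity * 1e6
  dv2 <- deconvolve_charge_series(ps_scaled, z_search = c(1, 40),
                                  tolerance = 5)
  expect_equal(dv2$neutral_mass, dv$neutral_mass)
})

test_that("a single peak with a fixed charge inverts in closed form", {
  mz <- (25000 + 10 * 1.00728) / 10
  dv <- deconvolve_charge_series(data.frame(mz = mz, intensity = 1),
                                 z_search = c(10, 10))
  expect_equal(dv$neutral_mass, 25000, tolerance = 1e-9)
  expect_error(deconvolve_charge_series(data.frame(mz = mz), c(5, 30)),
               ">= 2 peaks")
  # impossible series: residual above tolerance is an error, not a guess
  bad <- data.frame(mz = c(1000, 1100, 3000), intensity = 1)
  expect_error(deconvolve_charge_series(bad, c(1, 40), tolerance = 1),
               "residual")
})
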