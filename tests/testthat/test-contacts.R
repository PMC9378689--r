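test_that("a linear N-H...O geometry yields exactly one hydrogen bond", {
  # Ser OG (donor/acceptor) against a backbone carbonyl O with antecedent C
  rows <- data.frame(
    serial = 1:3, name = c("OG", "O", "C"), elem = c("O", "O", "C"),
    resid = c("SER", "GLY", "GLY"), chain = c("P", "Q", "Q"),
    resno = c(1L, 1L, 1L), insert = "",
    x = c(0, 2.9, 4.1), y = 0, z = 0, occ = 1, alt = "", het = FALSE)
  m <- structure_model(rows, id = "hb")
  ct <- detect_polar_contacts(m, selection("P"), selection("Q"))
  expect_equal(nrow(ct), 1L)
  expect_equal(ct$kind, "hbond")
  expect_equal(ct$distance, 2.9, tolerance = 1e-9)
})

test_that("the acceptor-antecedent angle criterion rejects head-on approach", {
  # antecedent C sits between donor and acceptor: angle < 90 degrees
  rows <- data.frame(
    serial = 1:3, name = c("OG", "O", "C"), elem = c("O", "O", "C"),
    resid = c("SER", "GLY", "GLY"), chain = c("P", "Q", "Q"),
    resno = c(1L, 1L, 1L), insert = "",
    x = c(0, 2.9, 1.6), y = c(0, 0, 0.4), z = 0, occ = 1, alt = "",
    het = FALSE)
  m <- structure_model(rows, id = "blocked")
  ct <- detect_polar_contacts(m, selection("P"), selection("Q"))
  expect_equal(nrow(ct), 0L)
})

test_that("an Arg guanidinium against phosphate is a salt bridge, not an hbond", {
  rows <- data.frame(
    serial = 1:3, name = c("NH1", "OP1", "P"), elem = c("N", "O", "P"),
    resid = c("ARG", "U", "U"), chain = c("P", "R", "R"),
    resno = c(77L, 35L, 35L), insert = "",
    x = c(0, 3.2, 4.7), y = 0, z = 0, occ = 1, alt = "", het = FALSE)
  m <- structure_model(rows, id = "sb")
  ct <- detect_polar_contacts(m, selection("P"), selection("R"))
  expect_equal(ct$kind, "salt_bridge")
  expect_equal(nrow(ct), 1L)
})

test_that("a cation over a base ring centroid registers a cation-pi contact", {
  g <- putkit:::base_template("G")
  base <- putkit:::residue_rows(g, "R", 35L, "G")
  lys <- data.frame(serial = 0L, name = "NZ", elem = "N", resid = "LYS",
                    chain = "P", resno = 79L, insert = "",
                    x = mean(g[c("N1","C2","N3","C4","C5","C6"), 1L]),
                    y = mean(g[c("N1","C2","N3","C4","C5","C6"), 2L]),
                    z = 4.0, occ = 1, alt = "", het = FALSE)
  rows <- rbind(base, lys)
  rows$serial <- seq_len(nrow(rows))
  m <- structure_model(rows, id = "catpi")
  ct <- detect_polar_contacts(m, selection("P"), selection("R"))
  cp <- ct[ct$kind == "cation_pi", ]
  expect_gte(nrow(cp), 1L)
  expect_true(all(cp$angle <= 30))
  expect_true(all(cp$distance <= 6))
  # moving the cation far off the ring normal kills the contact
  m2 <- m
  m2$atoms$x[m2$atoms$name == "NZ"] <- m2$atoms$x[m2$atoms$name == "NZ"] + 5.5
  m2$atoms$z[m2$atoms$name == "NZ"] <- 0.5
  ct2 <- detect_polar_contacts(m2, selection("P"), selection("R"))
  expect_equal(sum(ct2$kind == "cation_pi"), 0L)
})

test_that("contact detection is invariant under rigid motion of the model", {
  fx <- make_duplex(n_pairs = 6L)
  a <- selection("A"); b <- selection("B")
  before <- detect_polar_contacts(fx$model, a, b)
  after <- detect_polar_contacts(rigidly_move(fx$model), a, b)
  expect_identical(before[, c("kind", "chain_a", "res_a", "atom_a",
                              "chain_b", "res_b", "atom_b")],
                   after[, c("kind", "chain_a", "res_a", "atom_a",
                             "chain_b", "res_b", "atom_b")])
  expect_equal(before$distance, after$distance, tolerance = 1e-6)
})

test_that("an empty contact list is a valid result", {
  far <- mk_model(c("CA", "CA"), "C", "ALA", c("A", "B"), c(1L, 1L),
                  rbind(c(0, 0, 0), c(60, 0, 0)))
  ct <- detect_polar_contacts(far, selection("A"), selection("B"))
  expect_equal(nrow(ct), 0L)
  expect_s3_class(ct, "ContactSet")
})
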