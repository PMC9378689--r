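# in-code fixture builders shared across test files

mk_model <- function(name, elem, resid, chain, resno, xyz, het = FALSE,
                     occ = 1, alt = "", id = "fixture") {
  n <- length(name)
  structure_model(data.frame(
    serial = seq_len(n), name = name, elem = elem, resid = resid,
    chain = chain, resno = resno, insert = "", x = xyz[, 1L], y = xyz[, 2L],
    z = xyz[, 3L], occ = occ, alt = alt, het = het,
    stringsAsFactors = FALSE), id = id)
}

# single-atom-per-residue cloud (pseudo-CA protein)
mk_cloud <- function(xyz, chain = "A", id = "cloud") {
  n <- nrow(xyz)
  mk_model(rep("CA", n), rep("C", n), rep("ALA", n), rep(chain, n),
           seq_len(n), xyz, id = id)
}

# model holding one constructed base pair (+ sugars), chains A/B
pair_model <- function(geom, base_i, base_j, res_i = 1L, res_j = 1L,
                       chain_i = "A", chain_j = "B") {
  sug_i <- putkit:::attach_sugar(geom$base_i,
                                 attr(putkit:::base_template(base_i), "glycosidic"))
  sug_j <- putkit:::attach_sugar(geom$base_j,
                                 attr(putkit:::base_template(base_j), "glycosidic"),
                                 normal_z = -1)
  rows <- rbind(
    putkit:::residue_rows(rbind(geom$base_i, sug_i), chain_i, res_i, base_i),
    putkit:::residue_rows(rbind(geom$base_j, sug_j), chain_j, res_j, base_j))
  rows$serial <- seq_len(nrow(rows))
  structure_model(rows, id = paste0("pair_", base_i, base_j))
}

rigidly_move <- function(model, axis = c(1, 2, 2), angle = 37,
                         shift = c(5, -3, 11)) {
  tr <- rigid_transform(rotation_from_axis_angle(axis, angle), shift)
  apply_transform(tr, model)
}

expect_same_atoms <- function(a, b, tol = 1e-3) {
  expect_equal(nrow(a$atoms), nrow(b$atoms))
  expect_identical(a$atoms$name, b$atoms$name)
  expect_identical(a$atoms$chain, b$atoms$chain)
  expect_identical(a$atoms$resno, b$atoms$resno)
  expect_lt(max(abs(as.matrix(a$atoms[, c("x", "y", "z")]) -
                      as.matrix(b$atoms[, c("x", "y", "z")]))), tol)
}
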