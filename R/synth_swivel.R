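# evaluate `expr` under a private RNG stream; the caller's RNG state is
# untouched, so generators are pure functions of their arguments + seed
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) rm(".Random.seed", envir = globalenv())
    else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Generate a two-module pseudo-C-alpha model with a known swivel rotation
#'
#' Emulates the geometry measured between elongation complexes: a rigid core
#' module, a rigid swivel module rotated about an axis through a
#' bridge-helix marker line, and optional i.i.d. Gaussian coordinate noise
#' on the target copy.  The returned `DomainSet` splits the swivel module
#' into the five canonical members so the fixture runs through the same code
#' path as deposited structures; ground truth is recorded alongside.
#'
#' @param n_core,n_swivel pseudo-atom counts (>= 50 each).
#' @param angle applied swivel angle in degrees, within [0, 20].
#' @param axis rotation axis direction (default parallel to the
#'   bridge-helix marker, +z).
#' @param noise_sigma Gaussian noise s.d. per coordinate (A), target only.
#' @param seed RNG seed; fixtures are bit-reproducible.
#' @return a `SwivelFixture`: `reference`, `target` (`StructureModel`s),
#'   `domains`, `true_angle`, `true_axis`, `axis_point`, `noise_sigma`,
#'   `seed`, `marked_tip` (chain/resno of the most-displaced swivel atom),
#'   `marked_tip_displacement`, `n_zbd_atoms`.
#' @export
make_two_module_model <- function(n_core = 300L, n_swivel = 200L, angle = 2.5,
                                  axis = c(0, 0, 1), noise_sigma = 0,
                                  seed = 1L) {
  if (n_core < 50L || n_swivel < 50L) stop("need >= 50 atoms per module")
  if (angle < 0 || angle > 20) stop("angle must lie in [0, 20] degrees")
  if (vnorm(axis) < 1e-9) stop("degenerate rotation axis")
  axis <- unit(axis)
  axis_point <- c(30, 0, 0)
  n_bh <- 30L
  with_seed(seed, {
    core_xyz <- cbind(rnorm(n_core, 0, 18), rnorm(n_core, 0, 18),
                      rnorm(n_core, 0, 18))
    sw_xyz <- cbind(rnorm(n_swivel, 60, 14), rnorm(n_swivel, 0, 14),
                    rnorm(n_swivel, 0, 14))
    bh_xyz <- cbind(rep(axis_point[1L], n_bh), rep(axis_point[2L], n_bh),
                    seq(-20, 20, length.out = n_bh)) +
      matrix(rnorm(3L * n_bh, 0, 0.3), n_bh, 3L)
    noise <- matrix(rnorm(3L * (n_core + n_swivel + n_bh), 0, 1),
                    ncol = 3L)
  })

  mk_atoms <- function(core, sw, bh) {
    xyz <- rbind(core, bh, sw)
    resno <- c(seq_len(n_core), 9000L + seq_len(n_bh),
               1000L + seq_len(n_swivel))
    data.frame(serial = seq_len(nrow(xyz)), name = "CA", elem = "C",
               resid = "ALA", chain = "C", resno = resno, insert = "",
               x = xyz[, 1L], y = xyz[, 2L], z = xyz[, 3L], occ = 1,
               alt = "", het = FALSE, stringsAsFactors = FALSE)
  }
  reference <- structure_model(mk_atoms(core_xyz, sw_xyz, bh_xyz),
                               id = "synthetic_reference")
  R <- rotation_from_axis_angle(axis, angle)
  sw_rot <- sweep(sweep(sw_xyz, 2L, axis_point) %*% t(R), 2L, axis_point, `+`)
  disp <- sqrt(rowSums((sw_rot - sw_xyz)^2))
  tip <- which.max(disp)
  tgt_atoms <- mk_atoms(core_xyz, sw_rot, bh_xyz)
  if (noise_sigma > 0) {
    tgt_atoms$x <- tgt_atoms$x + noise_sigma * noise[, 1L]
    tgt_atoms$y <- tgt_atoms$y + noise_sigma * noise[, 2L]
    tgt_atoms$z <- tgt_atoms$z + noise_sigma * noise[, 3L]
  }
  target <- structure_model(tgt_atoms, id = "synthetic_target")

  fifth <- function(k) {                      # k-th fifth of the swivel range
    lo <- floor((k - 1L) * n_swivel / 5) + 1L
    hi <- floor(k * n_swivel / 5)
    sprintf("C:%d-%d", 1000L + lo, 1000L + hi)
  }
  domains <- domain_set(list(
    core = sprintf("C:1-%d C:9001-%d", n_core, 9000L + n_bh),
    clamp = fifth(1L), shelf = fifth(2L), jaw = fifth(3L), SI3 = fifth(4L),
    betaprime_cterm = fifth(5L),
    bridge_helix = sprintf("C:9001-%d", 9000L + n_bh),
    ZBD = "C:1001-1020"), name = "synthetic_two_module")

  structure(list(reference = reference, target = target, domains = domains,
                 true_angle = angle, true_axis = axis,
                 axis_point = axis_point, noise_sigma = noise_sigma,
                 seed = seed,
                 marked_tip = list(chain = "C", resno = 1000L + tip),
                 marked_tip_displacement = disp[tip],
                 n_zbd_atoms = 20L),
            class = "SwivelFixture")
}
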