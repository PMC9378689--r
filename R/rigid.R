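#' Rigid transforms
#'
#' A `RigidTransform` is a proper rotation (3x3, det +1) plus a translation
#' in Angstrom, applied as `x %*% t(R) + t`.
#'
#' @param rotation 3x3 orthonormal matrix with determinant +1.
#' @param translation length-3 numeric.
#' @return an object of class `RigidTransform`.
#' @export
rigid_transform <- function(rotation = diag(3), translation = c(0, 0, 0)) {
  rotation <- as.matrix(rotation)
  if (!all(dim(rotation) == c(3L, 3L))) stop("rotation must be 3x3")
  if (max(abs(rotation %*% t(rotation) - diag(3))) > 1e-6)
    stop("rotation matrix is not orthonormal")
  if (abs(det(rotation) - 1) > 1e-6)
    stop("rotation matrix must have determinant +1 (no reflections)")
  structure(list(rotation = rotation, translation = as.numeric(translation)),
            class = "RigidTransform")
}

#' Apply a rigid transform to coordinates
#'
#' @param transform a `RigidTransform`.
#' @param xyz n x 3 coordinate matrix (or a `StructureModel`).
#' @return transformed coordinates (or model).
#' @export
apply_transform <- function(transform, xyz) {
  if (inherits(xyz, "StructureModel")) {
    m <- xyz
    new_xyz <- apply_transform(transform, atom_xyz(m$atoms))
    m$atoms$x <- new_xyz[, 1L]; m$atoms$y <- new_xyz[, 2L]
    m$atoms$z <- new_xyz[, 3L]
    return(m)
  }
  sweep(xyz %*% t(transform$rotation), 2L, transform$translation, `+`)
}

# pair two atom tables by (chain, resno, insert, name); drops unmatched rows
# symmetrically and reports how many were dropped
pair_by_identity <- function(mobile, reference) {
  key_m <- paste(mobile$chain, mobile$resno, mobile$insert, mobile$name)
  key_r <- paste(reference$chain, reference$resno, reference$insert, reference$name)
  shared <- intersect(key_m, key_r)
  list(mobile = mobile[match(shared, key_m), , drop = FALSE],
       reference = reference[match(shared, key_r), , drop = FALSE],
       n_dropped = (length(key_m) - length(shared)) + (length(key_r) - length(shared)))
}

#' Least-squares rigid superposition (Kabsch)
#'
#' Finds the proper rotation + translation minimising the RMSD of `mobile`
#' onto `reference`.  Reflections are excluded.  With
#' `pairing = "by_identity"` atoms are matched by
#' (chain, residue number, insertion code, atom name) and unmatched atoms are
#' dropped symmetrically; `"by_order"` pairs row i with row i.
#'
#' @param mobile,reference atom data frames (from [select_atoms()]) or n x 3
#'   coordinate matrices.
#' @param pairing `"by_order"` or `"by_identity"`.
#' @return a `SuperpositionResult`: `transform`, `rmsd`, `n_atoms`,
#'   `atom_pairing` (list with `mode` and `n_dropped`).
#' @export
kabsch_superpose <- function(mobile, reference,
                             pairing = c("by_order", "by_identity")) {
  pairing <- match.arg(pairing)
  n_dropped <- 0L
  if (is.data.frame(mobile) && is.data.frame(reference) &&
      pairing == "by_identity") {
    p <- pair_by_identity(mobile, reference)
    if (nrow(p$mobile) == 0L) {
      key_m <- paste(mobile$chain, mobile$resno, mobile$name)
      stop("identity pairing matched no atoms; first mobile atom was ", key_m[1L])
    }
    mobile <- p$mobile; reference <- p$reference; n_dropped <- p$n_dropped
  }
  P <- if (is.data.frame(mobile)) atom_xyz(mobile) else as.matrix(mobile)
  Q <- if (is.data.frame(reference)) atom_xyz(reference) else as.matrix(reference)
  if (nrow(P) != nrow(Q))
    stop(sprintf("atom counts differ after pairing (%d vs %d)", nrow(P), nrow(Q)))
  if (nrow(P) < 3L) stop("need at least 3 atom pairs for superposition")
  cp <- colMeans(P); cq <- colMeans(Q)
  P0 <- sweep(P, 2L, cp); Q0 <- sweep(Q, 2L, cq)
  sv <- svd(crossprod(P0, Q0))        # H = P0^T Q0 ; R = V S U^T
  if (sv$d[2L] < 1e-9 * max(sv$d[1L], 1e-300))
    stop("degenerate (collinear) atom configuration: superposition ill-defined")
  d <- sign(det(sv$v %*% t(sv$u)))
  R <- sv$v %*% diag(c(1, 1, d)) %*% t(sv$u)
  tr <- as.numeric(cq - R %*% cp)
  resid <- Q0 - P0 %*% t(R)
  rmsd <- sqrt(sum(resid^2) / nrow(P))
  structure(list(transform = rigid_transform(R, tr), rmsd = rmsd,
                 n_atoms = nrow(P),
                 atom_pairing = list(mode = pairing, n_dropped = n_dropped)),
            class = "SuperpositionResult")
}

#' @export
print.SuperpositionResult <- function(x, ...) {
  cat(sprintf("Superposition of %d atom pairs: rmsd %.3f A (rotation %.2f deg)\n",
              x$n_atoms, x$rmsd, rotation_angle(x$transform$rotation)))
  invisible(x)
}

check_rotation <- function(R) {
  R <- as.matrix(R)
  if (!all(dim(R) == c(3L, 3L)) ||
      max(abs(R %*% t(R) - diag(3))) > 1e-6 || abs(det(R) - 1) > 1e-6)
    stop("input is not a proper rotation matrix")
  R
}

#' Rotation angle of a rotation matrix
#'
#' `theta = acos((trace(R) - 1) / 2)`, clamped, in degrees on `[0, 180]`.
#'
#' @param R 3x3 proper rotation matrix (or a `RigidTransform`).
#' @return angle in degrees.
#' @export
rotation_angle <- function(R) {
  if (inherits(R, "RigidTransform")) R <- R$rotation
  R <- check_rotation(R)
  # atan2 form: accurate at both ends of [0, 180], unlike plain acos
  v <- c(R[3L, 2L] - R[2L, 3L], R[1L, 3L] - R[3L, 1L], R[2L, 1L] - R[1L, 2L])
  atan2(vnorm(v) / 2, (sum(diag(R)) - 1) / 2) * 180 / pi
}

#' Rotation axis and angle of a rotation matrix
#'
#' The axis sign is chosen so the reported angle is positive; when
#' `reference_direction` is supplied the axis is flipped, if needed, to have
#' a positive dot product with it (the swivel convention uses the
#' bridge-helix axis as the reference direction).
#'
#' @param R 3x3 proper rotation matrix (or a `RigidTransform`).
#' @param reference_direction optional length-3 vector fixing the axis sign.
#' @param tol_deg angle below which the axis is undefined (default 1e-6).
#' @return list with `axis` (unit vector) and `angle_deg`.
#' @export
rotation_axis <- function(R, reference_direction = NULL, tol_deg = 1e-6) {
  if (inherits(R, "RigidTransform")) R <- R$rotation
  R <- check_rotation(R)
  angle <- rotation_angle(R)
  if (angle <= tol_deg)
    stop("rotation angle ~0 (", format(angle), " deg): axis undefined")
  v <- c(R[3L, 2L] - R[2L, 3L], R[1L, 3L] - R[3L, 1L], R[2L, 1L] - R[1L, 2L])
  if (vnorm(v) > 1e-8) {
    axis <- unit(v)
  } else {
    # angle ~180: axis from the +1 eigenvector of (R + I)/2
    M <- (R + diag(3)) / 2
    axis <- unit(M[, which.max(diag(M))])
  }
  if (!is.null(reference_direction) && sum(axis * reference_direction) < 0)
    axis <- -axis
  list(axis = axis, angle_deg = angle)
}

#' Rotation matrix from axis and angle
#'
#' Rodrigues construction; inverse of [rotation_axis()] on `[0, 180]` degrees.
#'
#' @param axis length-3 direction (normalised internally).
#' @param angle_deg rotation angle in degrees.
#' @return 3x3 rotation matrix.
#' @export
rotation_from_axis_angle <- function(axis, angle_deg) {
  u <- unit(axis)
  th <- angle_deg * pi / 180
  K <- matrix(c(0, -u[3L], u[2L], u[3L], 0, -u[1L], -u[2L], u[1L], 0),
              3L, 3L, byrow = TRUE)
  diag(3) + sin(th) * K + (1 - cos(th)) * (K %*% K)
}
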