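# internal helpers shared across modules

`%||%` <- function(a, b) if (is.null(a)) b else a

vnorm <- function(v) sqrt(sum(v * v))

unit <- function(v) {
  n <- vnorm(v)
  if (n < 1e-12) stop("cannot normalise a zero-length vector")
  v / n
}

stopifnot_scalar_number <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    stop(sprintf("'%s' must be a single finite number", name))
}

# least-squares principal axis through a point cloud; oriented so that the
# axis points from the first toward the last row (N->C for helices)
principal_axis <- function(xyz) {
  if (nrow(xyz) < 2L) stop("need at least 2 points to fit an axis")
  ctr <- colMeans(xyz)
  s <- svd(sweep(xyz, 2L, ctr))
  ax <- s$v[, 1L]
  if (sum(ax * (xyz[nrow(xyz), ] - xyz[1L, ])) < 0) ax <- -ax
  list(point = ctr, direction = unit(ax))
}

angle_between_deg <- function(u, v) {
  cosang <- sum(unit(u) * unit(v))
  acos(max(-1, min(1, cosang))) * 180 / pi
}
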