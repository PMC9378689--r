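# independent quaternion oracle for rotation composition/extraction
quat_from_axis_angle <- function(axis, deg) {
  axis <- axis / sqrt(sum(axis^2))
  th <- deg * pi / 180
  c(cos(th / 2), sin(th / 2) * axis)
}
quat_mul <- function(q, r) {
  c(q[1] * r[1] - sum(q[2:4] * r[2:4]),
    q[1] * r[2:4] + r[1] * q[2:4] +
      c(q[3] * r[4] - q[4] * r[3],
        q[4] * r[2] - q[2] * r[4],
        q[2] * r[3] - q[3] * r[2]))
}
quat_angle_deg <- function(q) 2 * acos(min(1, abs(q[1]))) * 180 / pi

test_that("superposing a set onto itself gives identity and zero rmsd", {
  set.seed(42)
  P <- matrix(rnorm(12), 4L, 3L)
  fit <- kabsch_superpose(P, P)
  expect_lt(fit$rmsd, 1e-9)
  expect_lt(max(abs(fit$transform$rotation - diag(3))), 1e-9)
  expect_lt(max(abs(fit$transform$translation)), 1e-9)
})

test_that("a constructed rotation + translation is recovered exactly", {
  set.seed(7)
  P <- matrix(rnorm(60, sd = 10), 20L, 3L)
  R <- rotation_from_axis_angle(c(0, 0, 1), 30)
  Q <- sweep(P %*% t(R), 2L, c(1, 2, 3), `+`)
  fit <- kabsch_superpose(P, Q)
  expect_lt(fit$rmsd, 1e-9)
  expect_lt(max(abs(apply_transform(fit$transform, P) - Q)), 1e-9)
  expect_equal(rotation_angle(fit$transform$rotation), 30, tolerance = 1e-9)
})

test_that("rmsd is invariant under rigid motion of both point sets", {
  set.seed(9)
  P <- matrix(rnorm(30), 10L, 3L)
  Q <- P + matrix(rnorm(30, sd = 0.5), 10L, 3L)
  base <- kabsch_superpose(P, Q)$rmsd
  for (k in 1:5) {
    tr <- rigid_transform(rotation_from_axis_angle(rnorm(3), runif(1, 0, 180)),
                          rnorm(3, sd = 20))
    moved <- kabsch_superpose(apply_transform(tr, P),
                              apply_transform(tr, Q))$rmsd
    expect_equal(moved, base, tolerance = 1e-9)
  }
})

test_that("degenerate and mismatched inputs are rejected", {
  line <- cbind(1:5, 0, 0)
  expect_error(kabsch_superpose(line, line + 1), "collinear|degenerate")
  expect_error(kabsch_superpose(matrix(0, 2, 3), matrix(0, 2, 3)), "3 atom")
  a <- mk_cloud(matrix(rnorm(30), 10L, 3L))
  b <- mk_cloud(matrix(rnorm(30), 10L, 3L), chain = "B")
  expect_error(kabsch_superpose(a$atoms, b$atoms, pairing = "by_identity"),
               "no atoms")
})

test_that("kabsch agrees with the bio3d reference fit on noisy pairs", {
  set.seed(13)
  P <- matrix(rnorm(90, sd = 8), 30L, 3L)
  Q <- sweep(P %*% t(rotation_from_axis_angle(c(1, 2, 3), 25)), 2L,
             c(4, -2, 9), `+`) + matrix(rnorm(90, sd = 0.2), 30L, 3L)
  ours <- kabsch_superpose(P, Q)$rmsd
  ref <- bio3d::rmsd(as.numeric(t(Q)), as.numeric(t(P)), fit = TRUE)
  expect_equal(ours, ref, tolerance = 1e-3)
})

test_that("rotation_angle matches closed forms and a quaternion oracle", {
  expect_equal(rotation_angle(diag(3)), 0)
  R180 <- rotation_from_axis_angle(c(1, 1, 0), 180)
  expect_equal(rotation_angle(R180), 180, tolerance = 1e-9)
  # composition of 10 deg about x then 20 deg about y
  Rc <- rotation_from_axis_angle(c(0, 1, 0), 20) %*%
    rotation_from_axis_angle(c(1, 0, 0), 10)
  q <- quat_mul(quat_from_axis_angle(c(0, 1, 0), 20),
                quat_from_axis_angle(c(1, 0, 0), 10))
  expect_equal(rotation_angle(Rc), quat_angle_deg(q), tolerance = 1e-9)
  expect_error(rotation_angle(matrix(1, 3, 3)), "not a proper rotation")
})

test_that("rotation_axis respects the sign convention and round-trips", {
  ax <- rotation_axis(rotation_from_axis_angle(c(0, 0, 1), 2.5))
  expect_equal(ax$angle_deg, 2.5, tolerance = 1e-9)
  expect_equal(as.numeric(ax$axis), c(0, 0, 1), tolerance = 1e-9)
  flipped <- rotation_axis(rotation_from_axis_angle(c(0, 0, 1), 2.5),
                           reference_direction = c(0, 0, -1))
  expect_equal(as.numeric(flipped$axis), c(0, 0, -1), tolerance = 1e-9)
  expect_equal(flipped$angle_deg, 2.5, tolerance = 1e-9)
  # axis/angle round-trip across random samples
  set.seed(31)
  for (k in 1:25) {
    u <- rnorm(3); u <- u / sqrt(sum(u^2))
    th <- runif(1, 0.01, 179.9)
    ax <- rotation_axis(rotation_from_axis_angle(u, th),
                        reference_direction = u)
    expect_equal(ax$angle_deg, th, tolerance = 1e-9)
    expect_equal(as.numeric(ax$axis), u, tolerance = 1e-7)
  }
  expect_error(rotation_axis(diag(3)), "undefined")
})
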