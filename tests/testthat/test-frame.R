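test_that("rim selection returns 19 points on the analytic rim circle", {
  case <- test_phantom()
  rim <- select_rim_points(case$native_mesh)
  expect_equal(nrow(rim), 19L)
  # distance to the ideal rim circle (centre at cup centre, plane normal =
  # polar axis, radius = cup radius)
  lat <- sqrt(rim[, 1]^2 + rim[, 2]^2)
  dcirc <- sqrt((lat - 25)^2 + rim[, 3]^2)
  expect_lt(max(dcirc), 1.0)
  # rim points lie on the cup sphere (up to ring interpolation)
  expect_lt(max(abs(sqrt(rowSums(rim^2)) - 25)), 0.1)
})

test_that("rim selection count is configurable and errors without a cup", {
  case <- test_phantom()
  expect_equal(nrow(select_rim_points(case$native_mesh, n_points = 31L)), 31L)
  # convex ellipsoid: no cup anywhere
  ell <- mesh_transform(icosphere(1, c(0, 0, 0), 3), diag(c(1, 1, 1)))
  ell$vertices <- ell$vertices %*% diag(c(30, 20, 15))
  expect_error(select_rim_points(ell), "no cup")
})

test_that("algebraic sphere fit is exact on noiseless points", {
  set.seed(11)
  u <- matrix(rnorm(19 * 3), 19)
  u <- u / sqrt(rowSums(u^2))
  pts <- sweep(u * 25, 2, c(1, 2, 3), "+")
  f <- fit_sphere(pts)
  expect_equal(f$centre, c(1, 2, 3), tolerance = 1e-9)
  expect_equal(f$radius, 25, tolerance = 1e-9)
})

test_that("sphere fit radius bias is below 1% under 0.5 mm noise", {
  set.seed(7)
  radii <- replicate(100, {
    u <- matrix(rnorm(19 * 3), 19)
    u <- u / sqrt(rowSums(u^2))
    pts <- sweep(u * 25, 2, c(1, 2, 3), "+") + matrix(rnorm(19 * 3, 0, 0.5), 19)
    fit_sphere(pts)$radius
  })
  expect_lt(abs(mean(radii) - 25) / 25, 0.01)
})

test_that("sphere fit rejects coplanar points", {
  th <- seq(0, 2 * pi, length.out = 20)[-20]
  pts <- cbind(cos(th), sin(th), 0)
  expect_error(fit_sphere(pts), "coplanar")
  expect_error(fit_sphere(cbind(c(0, 1, 2, 3), c(0, 1, 2, 3), 0)), "degenerate|coplanar")
})

cross3 <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2], a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

test_that("frame axes are orthonormal and match the phantom", {
  case <- test_phantom()
  fr <- frame_from_mesh(case$native_mesh)
  A <- cbind(fr$superior_axis, fr$anterior_axis, fr$polar_axis)
  expect_equal(crossprod(A), diag(3), tolerance = 1e-9, ignore_attr = TRUE)
  # right-handed: superior x anterior = polar
  expect_equal(cross3(fr$superior_axis, fr$anterior_axis), fr$polar_axis,
               tolerance = 1e-9)
  expect_lt(acos(min(sum(fr$polar_axis * c(0, 0, 1)), 1)) * 180 / pi, 2)
  expect_lt(sqrt(sum(fr$hjc^2)), 0.5)
  expect_lt(abs(fr$radius - 25) / 25, 0.02)
})

test_that("frame estimation is equivariant under rigid transforms", {
  case <- test_phantom()
  fr0 <- frame_from_mesh(case$native_mesh)
  set.seed(3)
  for (k in 1:5) {
    ax <- rnorm(3); ax <- ax / sqrt(sum(ax^2))
    R <- acetrecon:::rotation_about(ax, runif(1, -0.5, 0.5))
    tr <- rnorm(3, 0, 20)
    m <- mesh_transform(case$native_mesh, R, tr)
    hint <- as.vector(R %*% c(1, 0, 0))
    fr <- frame_from_mesh(m, body_axes_hint = hint)
    expect_lt(acos(min(sum(fr$polar_axis * (R %*% fr0$polar_axis)), 1)) *
                180 / pi, 2)
    expect_lt(max(abs(fr$hjc - (as.vector(R %*% fr0$hjc) + tr))), 0.5)
    expect_lt(abs(fr$radius - fr0$radius), 0.2)
  }
})

test_that("excision sphere has the exact 2.5x radius at the HJC", {
  fr <- acetabular_frame(c(3, -2, 7), 25, c(0, 0, 1), c(1, 0, 0))
  ex <- excision_sphere(fr)
  expect_equal(max(sqrt(rowSums(sweep(ex$vertices, 2, fr$hjc)^2))), 62.5,
               tolerance = 1e-9)
  expect_equal(min(sqrt(rowSums(sweep(ex$vertices, 2, fr$hjc)^2))), 62.5,
               tolerance = 1e-9)
  v <- 4 / 3 * pi * 62.5^3
  expect_lt(abs(mesh_volume(ex) - v) / v, 0.005)
  # centroid = hjc
  expect_equal(colMeans(ex$vertices), fr$hjc, tolerance = 1e-9)
})
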