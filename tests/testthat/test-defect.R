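frame25 <- acetabular_frame(c(0, 0, 0), 25, c(0, 0, 1), c(1, 0, 0))

test_that("ray generation covers the sphere near-uniformly", {
  rays <- generate_rays(frame25, angular_spacing = 1)
  n <- nrow(rays$directions)
  expect_gt(n, 35000)
  expect_lt(n, 48000)
  expect_lt(max(abs(sqrt(rowSums(rays$directions^2)) - 1)), 1e-12)
  expect_equal(rays$max_range, 62.5)
  # doubling the spacing reduces the count by ~4x
  n2 <- nrow(generate_rays(frame25, angular_spacing = 2)$directions)
  expect_equal(n / n2, 4, tolerance = 0.02)
  expect_error(generate_rays(frame25, angular_spacing = 0.05))
})

test_that("ray classification reproduces set-difference interval algebra", {
  # native solid on (20, 40), pathological on (30, 40): defect (20, 30)
  cl <- classify_ray(c(20, 40), c(30, 40), max_range = 62.5)
  expect_true(cl$valid)
  expect_equal(cl$intervals, matrix(c(20, 30), 1), ignore_attr = TRUE)
  expect_equal(sort(cl$points_t), c(20, 25, 30))

  # pathological bone entirely gone: whole native interval is defect
  cl2 <- classify_ray(c(20, 40), numeric(0), max_range = 62.5)
  expect_equal(cl2$intervals, matrix(c(20, 40), 1), ignore_attr = TRUE)

  # identical solids: no defect
  cl3 <- classify_ray(c(20, 40), c(20, 40), max_range = 62.5)
  expect_equal(nrow(cl3$intervals), 0L)

  # odd hit count: solid continues beyond range, interval closes there
  cl4 <- classify_ray(25, numeric(0), max_range = 62.5)
  expect_equal(cl4$intervals, matrix(c(25, 62.5), 1), ignore_attr = TRUE)

  # truncation at the intersection cap cannot be resolved
  cl5 <- classify_ray(c(5, 10, 15, 20), c(5, 10), max_range = 62.5,
                      native_truncated = TRUE)
  expect_false(cl5$valid)
  expect_equal(nrow(cl5$intervals), 0L)
})

test_that("classify_ray agrees exactly with a dense-sampling oracle", {
  set.seed(99)
  max_range <- 60
  ts <- seq(0.05, max_range - 0.05, by = 0.1) + 0.013 # avoid hit coincidences
  for (rep in seq_len(2000)) {
    nh <- sort(round(runif(sample(0:4, 1), 0, max_range), 1))
    ph <- sort(round(runif(sample(0:4, 1), 0, max_range), 1))
    nh <- unique(nh); ph <- unique(ph)
    cl <- classify_ray(nh, ph, max_range)
    expect_identical(interval_membership(cl$intervals, ts),
                     interval_oracle(nh, ph, max_range, ts))
  }
})

test_that("single-linkage clustering discards clusters below the floor", {
  set.seed(5)
  blob <- function(centre, n, sd = 2) sweep(matrix(rnorm(n * 3, 0, sd), n), 2,
                                            centre, "+")
  pts <- rbind(blob(c(0, 0, 0), 1000), blob(c(50, 0, 0), 300),
               blob(c(0, 50, 0), 199))
  cl <- cluster_points(pts, linkage_radius = 5, min_size = 200L)
  expect_length(cl, 2L)
  expect_equal(vapply(cl, nrow, integer(1)), c(1000L, 300L))
  # everything below the floor: empty result with warning
  expect_warning(cl2 <- cluster_points(blob(c(0, 0, 0), 150), 5), "no defect")
  expect_length(cl2, 0L)
})

test_that("surface reconstruction recovers a sampled ball and the hull limit", {
  set.seed(21)
  u <- matrix(rnorm(4000 * 3), 4000)
  u <- u / sqrt(rowSums(u^2))
  r <- 10 * runif(4000)^(1 / 3)          # volumetric samples of a 10 mm ball
  pts <- u * r
  m <- reconstruct_surface(pts, alpha = 3, pitch = 0.5)
  expect_true(mesh_is_watertight(m))
  v <- 4 / 3 * pi * 1000
  expect_lt(abs(mesh_volume(m) - v) / v, 0.10)

  # alpha >> feature size on a convex cloud: converges to the convex hull
  cube_pts <- as.matrix(expand.grid(x = seq(0, 10, 1), y = seq(0, 10, 1),
                                    z = seq(0, 10, 1)))
  mc <- reconstruct_surface(cube_pts, alpha = 40, pitch = 0.5)
  expect_lt(abs(mesh_volume(mc) - 1000) / 1000, 0.12)

  # near-planar cluster is rejected
  flat <- cbind(matrix(runif(600 * 2, 0, 20), 600), 0)
  expect_error(reconstruct_surface(flat, alpha = 3, pitch = 0.5),
               "near-planar")
})

test_that("Boolean refinement preserves contained defects and rejects crumbs", {
  native <- icosphere(30, c(0, 0, 0), 4)
  patho <- icosphere(6, c(20, 0, 0), 4)      # far from the defect
  defect <- icosphere(10, c(0, 0, 0), 4)     # inside native, disjoint from patho
  dm <- refine_booleans(defect, patho, native, pitch = 0.5)
  expect_true(mesh_is_watertight(dm$mesh))
  expect_lt(abs(dm$volume - mesh_volume(defect) / 1000) /
              (mesh_volume(defect) / 1000), 0.005)

  # defect partially outside native: intersection cannot increase volume
  defect2 <- icosphere(10, c(25, 0, 0), 4)
  dm2 <- refine_booleans(defect2, patho, native, pitch = 0.5)
  expect_lt(dm2$volume, mesh_volume(defect2) / 1000)

  # fragment filter drops the small disconnected piece
  two <- local({
    a <- icosphere(10, c(0, 0, 0), 3)
    b <- icosphere(2.5, c(0, 0, 20), 3)
    surface_mesh(rbind(a$vertices, b$vertices),
                 rbind(a$faces, b$faces + nrow(a$vertices)))
  })
  dm3 <- refine_booleans(two, patho, native, pitch = 0.5,
                         min_component_cm3 = 0.5)
  expect_equal(mesh_components(dm3$mesh), 1L)
  expect_lt(abs(dm3$volume - 4 / 3 * pi), 0.1)  # the 10 mm ball only, cm^3
})
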