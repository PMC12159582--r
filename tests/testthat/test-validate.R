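test_that("dice identities: identical, disjoint, nested half-volume", {
  g <- voxel_grid(c(0, 0, 0), c(20, 20, 20), 1)
  mk <- function(rng) {
    m <- array(FALSE, c(20, 20, 20))
    m[rng[[1]], rng[[2]], rng[[3]]] <- TRUE
    attr(m, "grid") <- g
    m
  }
  a <- mk(list(1:10, 1:10, 1:10))
  expect_equal(dice(a, a), 1)
  b <- mk(list(11:20, 1:10, 1:10))
  expect_equal(dice(a, b), 0)
  # nested boxes, inner half the volume of outer: 2 * 0.5 / 1.5
  outer <- mk(list(1:10, 1:10, 1:10))
  inner <- mk(list(1:10, 1:10, 1:5))
  expect_equal(dice(outer, inner), 2 * 0.5 / 1.5, tolerance = 1e-12)
  # both empty counts as agreement
  e <- mk(list(integer(0), integer(0), integer(0)))
  expect_equal(dice(e, e), 1)
  g2 <- voxel_grid(c(1, 0, 0), c(20, 20, 20), 1)
  a2 <- a; attr(a2, "grid") <- g2
  expect_error(dice(a, a2), "different grids")
})

test_that("dice is symmetric", {
  set.seed(2)
  g <- voxel_grid(c(0, 0, 0), c(10, 10, 10), 1)
  a <- array(runif(1000) < 0.3, c(10, 10, 10)); attr(a, "grid") <- g
  b <- array(runif(1000) < 0.3, c(10, 10, 10)); attr(b, "grid") <- g
  expect_equal(dice(a, b), dice(b, a))
})

test_that("volume errors are plain absolute and relative differences", {
  expect_equal(volume_errors(50, 50), list(mae = 0, mare_pct = 0))
  expect_equal(volume_errors(50, 40), list(mae = 10, mare_pct = 25))
  expect_true(is.na(volume_errors(5, 0)$mare_pct))
  # aggregate mean over cases = arithmetic mean of per-case values
  cases <- list(c(50, 40), c(30, 30), c(10, 8))
  maes <- vapply(cases, function(x) volume_errors(x[1], x[2])$mae, numeric(1))
  expect_equal(mean(maes), mean(c(10, 0, 2)))
})

test_that("sampled Hausdorff distance matches closed forms", {
  a <- icosphere(10, c(0, 0, 0), 4)
  expect_lt(hausdorff_distance(a, a, sample_density = 5), 1e-9)
  b <- icosphere(12, c(0, 0, 0), 4)
  h <- hausdorff_distance(a, b, sample_density = 5)
  expect_equal(as.numeric(h), 2.0, tolerance = 0.1)
  # translation bound: H(A, B + t) <= H(A, B) + |t|
  b2 <- mesh_transform(b, translation = c(1.5, 0, 0))
  h2 <- hausdorff_distance(a, b2, sample_density = 5)
  expect_lte(as.numeric(h2), as.numeric(h) + 1.5 + 1e-6)
  # symmetry
  expect_equal(as.numeric(hausdorff_distance(b, a, sample_density = 5)),
               as.numeric(h), tolerance = 1e-9)
  empty <- surface_mesh(matrix(numeric(0), 0, 3), matrix(integer(0), 0, 3))
  expect_error(hausdorff_distance(a, empty), "empty")
})

test_that("voxelize on a shared grid supports mask comparison", {
  s <- icosphere(10, c(0.2, 0.1, -0.3), 4)
  g <- grid_for_meshes(list(s), 0.5)
  m <- voxelize(s, grid = g)
  expect_lt(abs(voxel_volume(m) - 4 / 3 * pi * 1000) / (4 / 3 * pi * 1000),
            0.02)
  # grid anchored at the reference bounding-box corner minus margin voxels
  expect_equal(g$origin, apply(s$vertices, 2, min) - 2 * 0.5)
  expect_error(voxelize(surface_mesh(s$vertices, s$faces[-1, , drop = FALSE]),
                        pitch = 1, name = "broken"), "broken")
})

test_that("validation report combines dice, volume errors and Hausdorff", {
  a <- icosphere(10, c(0, 0, 0), 4)
  b <- icosphere(10.5, c(0.3, 0, 0), 4)
  v <- validate_defect(b, a, pitch = 1)
  expect_gt(v$dice, 0.9)
  expect_equal(v$volume_mae, abs(mesh_volume(b) - mesh_volume(a)) / 1000,
               tolerance = 1e-9)
  expect_lt(v$hausdorff, 1.2)
  expect_gt(v$hausdorff, 0.2)
})
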