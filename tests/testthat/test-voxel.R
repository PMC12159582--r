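test_that("voxelization counts match closed-form volumes", {
  # axis-aligned 10 mm cube aligned to the grid -> exactly 1000 unit voxels
  g <- voxel_grid(c(0, 0, 0), c(12, 12, 12), 1)
  cube_mask <- array(FALSE, c(12, 12, 12))
  cube_mask[2:11, 2:11, 2:11] <- TRUE
  attr(cube_mask, "grid") <- g
  cube <- voxel_surface(cube_mask, g)
  m <- voxelize(cube, grid = g)
  expect_identical(sum(m), 1000L)

  s <- icosphere(10, c(0, 0, 0), 4)
  ms <- voxelize(s, pitch = 0.5)
  expect_lt(abs(voxel_volume(ms) - 4 / 3 * pi * 1000) / (4 / 3 * pi * 1000),
            0.02)
})

test_that("voxel surfacing is watertight with volume = count * pitch^3", {
  s <- icosphere(9, c(0.3, -0.2, 0.1), 3)
  m <- voxelize(s, pitch = 0.5)
  srf <- voxel_surface(m)
  expect_true(mesh_is_watertight(srf))
  expect_equal(mesh_volume(srf), voxel_volume(m), tolerance = 1e-9)
})

test_that("diagonal-contact masks are repaired to manifold surfaces", {
  g <- voxel_grid(c(0, 0, 0), c(4, 4, 4), 1)
  m <- array(FALSE, c(4, 4, 4))
  m[2, 2, 2] <- TRUE
  m[3, 3, 2] <- TRUE   # edge-diagonal contact
  attr(m, "grid") <- g
  raw <- acetrecon:::cpp_voxel_surface(as.logical(m), g$dims, g$origin, g$pitch)
  expect_false(mesh_is_watertight(surface_mesh(raw$vertices, raw$faces)))
  fixed <- acetrecon:::voxel_repair(m, g)
  expect_true(mesh_is_watertight(voxel_surface(fixed, g)))
  expect_true(all(m[fixed == FALSE] == FALSE))  # repair only adds voxels
})

test_that("voxel Boolean engine matches closed forms", {
  a <- icosphere(10, c(0, 0, 0), 4)
  b <- icosphere(5, c(0, 0, 0), 4)
  d <- mesh_boolean("difference", a, b, pitch = 0.25)
  expect_true(mesh_is_watertight(d$mesh))
  expect_lt(abs(d$volume - 4 / 3 * pi * (1000 - 125)) /
              (4 / 3 * pi * (1000 - 125)), 0.01)
  i <- mesh_boolean("intersection", a, b, pitch = 0.25)
  expect_lt(abs(i$volume - 4 / 3 * pi * 125) / (4 / 3 * pi * 125), 0.01)
  u <- mesh_boolean("union", a, b, pitch = 0.25)  # b nested in a
  expect_lt(abs(u$volume - 4 / 3 * pi * 1000) / (4 / 3 * pi * 1000), 0.01)
  # disjoint solids intersect to nothing
  c_ <- icosphere(3, c(30, 0, 0), 3)
  expect_equal(mesh_boolean("intersection", a, c_, pitch = 0.5)$volume, 0)
})

test_that("morphology round-trips and cavity filling behave", {
  s <- icosphere(8, c(0, 0, 0), 3)
  m <- voxelize(s, pitch = 0.5)
  dil <- acetrecon:::voxel_dilate(m, 2)
  ero <- acetrecon:::voxel_erode(dil, 2)
  # closing is conservative: contains the original, stays close in volume
  expect_true(all(ero[m]))
  expect_lt(voxel_volume(ero) / voxel_volume(m), 1.10)

  # hollow shell: cavity filled to the full ball
  inner <- icosphere(5, c(0, 0, 0), 3)
  g <- attr(m, "grid")
  shell <- m & !voxelize(inner, grid = g)
  shell <- acetrecon:::mask_with_grid(shell, g)
  filled <- acetrecon:::voxel_fill_cavities(shell)
  expect_equal(sum(filled), sum(m))
})
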