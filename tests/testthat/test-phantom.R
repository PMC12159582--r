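test_that("phantom construction is watertight, deterministic, and analytic", {
  case <- test_phantom()
  m <- case$native_mesh
  expect_true(mesh_is_watertight(m))
  expect_equal(mesh_components(m), 1L)
  expect_gt(mesh_volume(m), 0)

  # same parameters give byte-identical vertices
  case2 <- make_phantom(phantom_params(block_half_extents = c(40, 40, 30),
                                       cup_radius = 25), seed = 99)
  expect_identical(m$vertices, case2$native_mesh$vertices)
  expect_identical(m$faces, case2$native_mesh$faces)

  # block 80 x 80 x 60, r = 25: volume = block - hemisphere, within 1% by
  # the voxel oracle at 0.5 mm pitch
  vo <- voxel_oracle(m, pitch = 0.5)
  v_true <- 80 * 80 * 60 - 2 / 3 * pi * 25^3
  expect_lt(abs(vo$volume - v_true) / v_true, 0.01)

  # truth frame equals the construction parameters
  expect_equal(case$truth_frame$hjc, c(0, 0, 0))
  expect_equal(case$truth_frame$radius, 25)
  expect_equal(case$truth_frame$polar_axis, c(0, 0, 1))
})

test_that("invalid phantom parameters are rejected", {
  expect_error(phantom_params(block_half_extents = c(20, 40, 30),
                              cup_radius = 25), "not contained")
  expect_error(phantom_params(cup_radius = -1), "positive")
  expect_error(phantom_params(polar_axis = c(0, 0, 1),
                              superior_axis = c(0, 0.5, 1)), "orthogonal")
})

test_that("carving matches closed forms and is monotone", {
  case <- test_phantom()
  # empty spec: identity
  c0 <- carve_defect(case, defect_spec(), pitch = 0.5)
  expect_identical(c0$pathological_mesh$vertices, case$native_mesh$vertices)
  expect_equal(c0$truth_defect_volume, 0)

  # sphere fully interior to bone: truth = (4/3) pi 10^3 up to a voxel shell
  sp <- defect_spec(defect_primitive("sphere", c(0, 0, -40), 10))
  c1 <- carve_defect(case, sp, pitch = 0.5)
  v <- 4 / 3 * pi * 1000
  shell <- 4 * pi * 100 * 0.5   # one-voxel-shell bound
  expect_lt(abs(c1$truth_defect_volume - v), shell)
  expect_true(mesh_is_watertight(c1$pathological_mesh))

  # union of overlapping spheres is strictly below the sum
  sp2 <- defect_spec(defect_primitive("sphere", c(0, 0, -40), 10),
                     defect_primitive("sphere", c(8, 0, -40), 10))
  c2 <- carve_defect(case, sp2, pitch = 0.5)
  expect_gt(c2$truth_defect_volume, c1$truth_defect_volume)  # monotone
  expect_lt(c2$truth_defect_volume, 2 * v)

  # truth voxels inside native and outside pathological; patho inside native
  g <- c1$truth_grid
  nm <- voxelize(case$native_mesh, grid = g)
  pm <- voxelize(c1$pathological_mesh, grid = g, check = FALSE)
  tm <- truth_mask(c1)
  expect_true(all(nm[tm]))
  expect_equal(sum(pm & tm), 0L)
  # pathological \subseteq native up to the one-voxel repair band
  outside <- pm & !nm
  expect_lt(sum(outside) / sum(pm), 1e-3)

  # non-overlapping primitive is dropped with a warning
  far <- defect_spec(defect_primitive("sphere", c(500, 0, 0), 5))
  expect_warning(c3 <- carve_defect(case, far, pitch = 1), "dropped")
  expect_equal(c3$truth_defect_volume, 0)
})

test_that("population sampling yields corresponded meshes with logged params", {
  expect_length(sample_population(0, seed = 1), 0L)
  pop <- test_population()
  expect_length(pop, 25L)
  nv <- vapply(pop, function(m) nrow(m$vertices), integer(1))
  expect_true(all(nv == nv[1]))
  prm <- attr(pop, "params")
  expect_equal(nrow(prm), 25L)
  # larger draw: generating radius concentrates at its nominal mean
  pop2 <- sample_population(200, seed = 3)
  expect_lt(abs(mean(attr(pop2, "params")$cup_radius) - 25), 0.5)
})

test_that("voxel oracle reproduces closed-form volumes and Booleans", {
  s1 <- icosphere(1, c(0, 0, 0), 4)
  v1 <- voxel_oracle(s1, pitch = 0.02)$volume
  expect_lt(abs(v1 - 4 / 3 * pi) / (4 / 3 * pi), 0.01)

  a <- icosphere(2, c(0, 0, 0), 4)
  b <- icosphere(1, c(0, 0, 0), 4)
  d <- voxel_oracle(a, b, "difference", pitch = 0.05)$volume
  expect_lt(abs(d - 4 / 3 * pi * 7) / (4 / 3 * pi * 7), 0.01)

  c_ <- icosphere(1, c(10, 0, 0), 3)
  expect_equal(voxel_oracle(a, c_, "intersection", pitch = 0.1)$volume, 0)

  expect_error(voxel_oracle(surface_mesh(a$vertices,
                                         a$faces[-1, , drop = FALSE]),
                            pitch = 0.5), "watertight.*meshA")
})
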