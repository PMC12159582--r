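test_that("primitive meshes are watertight with closed-form volumes", {
  s <- icosphere(10, c(1, 2, 3), 4)
  expect_true(mesh_is_watertight(s))
  expect_equal(mesh_components(s), 1L)
  # geodesic sphere volume converges to (4/3) pi r^3 from below
  expect_lt(abs(mesh_volume(s) - 4 / 3 * pi * 1000) / (4 / 3 * pi * 1000),
            0.005)
  expect_lt(abs(mesh_area(s) - 4 * pi * 100) / (4 * pi * 100), 0.01)

  cy <- cylinder_mesh(5, c(1, -2, 0), c(0, 0, 1), 12, n = 128L)
  expect_true(mesh_is_watertight(cy))
  expect_lt(abs(mesh_volume(cy) - pi * 25 * 12) / (pi * 25 * 12), 0.002)
})

test_that("rigid transforms preserve volume and compose as expected", {
  s <- icosphere(8, c(0, 0, 0), 3)
  R <- acetrecon:::rotation_about(c(1, 1, 0), 0.7)
  m <- mesh_transform(s, R, c(5, -3, 2))
  expect_equal(mesh_volume(m), mesh_volume(s), tolerance = 1e-10)
  expect_equal(colMeans(m$vertices), c(5, -3, 2), tolerance = 1e-8)
  m2 <- mesh_transform(s, scale = 2)
  expect_equal(mesh_volume(m2), 8 * mesh_volume(s), tolerance = 1e-10)
})

test_that("STL round-trip preserves geometry and topology", {
  s <- icosphere(7, c(1, 1, 1), 2)
  f <- tempfile(fileext = ".stl")
  write_stl(s, f)
  s2 <- read_stl(f)
  expect_true(mesh_is_watertight(s2))
  expect_equal(mesh_volume(s2), mesh_volume(s), tolerance = 1e-9)
  expect_equal(nrow(s2$vertices), nrow(s$vertices))
  unlink(f)
})

test_that("watertightness check rejects open and non-manifold surfaces", {
  s <- icosphere(5, c(0, 0, 0), 2)
  open_mesh <- surface_mesh(s$vertices, s$faces[-1, , drop = FALSE])
  expect_false(mesh_is_watertight(open_mesh))
  dup <- surface_mesh(s$vertices, rbind(s$faces, s$faces[1, ]))
  expect_false(mesh_is_watertight(dup))
})

test_that("ray casting returns sorted in-range hits", {
  s <- icosphere(10, c(1, 2, 3), 4)
  r <- cast_ray(c(1, 2, 3), c(0.3, 0.5, -0.8), s)
  expect_length(r$hits, 1L)
  expect_equal(r$hits, 10, tolerance = 1e-2)

  # shell: origin at centre sees both surfaces
  inner <- icosphere(5, c(1, 2, 3), 4)
  h_out <- cast_ray(c(1, 2, 3), c(1, 0, 0), s)$hits
  h_in <- cast_ray(c(1, 2, 3), c(1, 0, 0), inner)$hits
  expect_equal(sort(c(h_in, h_out)), c(5, 10), tolerance = 1e-2)

  # range cutoff
  expect_length(cast_ray(c(1, 2, 3), c(1, 0, 0), s, max_range = 8)$hits, 0L)
})

test_that("intersection cap keeps the first four hits and flags truncation", {
  # five concentric spheres -> 5 crossings along any ray from the centre;
  # merge into one mesh with shells at radii 2, 4, 6, 8, 10
  radii <- c(2, 4, 6, 8, 10)
  meshes <- lapply(radii, function(r) icosphere(r, c(0, 0, 0), 3))
  off <- 0L
  V <- NULL; F <- NULL
  for (m in meshes) {
    V <- rbind(V, m$vertices)
    F <- rbind(F, m$faces + off)
    off <- off + nrow(m$vertices)
  }
  nested <- surface_mesh(V, F)
  r <- cast_ray(c(0, 0, 0), c(0, 0, 1), nested, max_hits = 4L)
  expect_length(r$hits, 4L)
  expect_true(r$truncated)
  expect_equal(r$hits, c(2, 4, 6, 8), tolerance = 0.02)
})
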