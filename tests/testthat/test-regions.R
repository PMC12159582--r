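frame_t <- acetabular_frame(c(0, 0, 0), 25, c(0, 0, 1), c(1, 0, 0))

test_that("region solids instantiate the published extents and are watertight", {
  rs <- define_regions(frame_t)
  for (nm in c("superior", "anterior", "posterior", "medial_wall"))
    expect_true(mesh_is_watertight(rs[[nm]]))

  # radial extents: 2.2r, 1.9r; cylinder radius 0.86r
  dmax <- function(m) max(sqrt(rowSums(m$vertices^2)))
  expect_equal(dmax(rs$superior), 2.2 * 25, tolerance = 1e-9)
  expect_equal(dmax(rs$anterior), 1.9 * 25, tolerance = 1e-9)
  expect_equal(dmax(rs$posterior), 1.9 * 25, tolerance = 1e-9)
  lat <- sqrt(rs$medial_wall$vertices[, 1]^2 + rs$medial_wall$vertices[, 2]^2)
  expect_equal(max(lat), 0.86 * 25, tolerance = 1e-6)

  # a 90-degree spherical wedge encloses a quarter of the ball volume
  v_wedge <- 0.25 * 4 / 3 * pi * (2.2 * 25)^3
  expect_lt(abs(mesh_volume(rs$superior) - v_wedge) / v_wedge, 0.01)
})

test_that("sector membership follows the dominant-axis rule symmetrically", {
  p_sup <- c(30, 5, 0); p_ant <- c(5, 30, 0); p_post <- c(5, -30, 0)
  memb <- acetrecon:::region_membership(rbind(p_sup, p_ant, p_post), frame_t)
  expect_equal(unname(memb[1, ]), c(TRUE, FALSE, FALSE, FALSE))
  expect_equal(unname(memb[2, ]), c(FALSE, TRUE, FALSE, FALSE))
  expect_equal(unname(memb[3, ]), c(FALSE, FALSE, TRUE, FALSE))
  # flipping the anterior axis swaps anterior/posterior membership
  fr2 <- acetabular_frame(c(0, 0, 0), 25, c(0, 0, 1), c(1, 0, 0))
  fr2$anterior_axis <- -fr2$anterior_axis
  memb2 <- acetrecon:::region_membership(rbind(p_ant, p_post), fr2)
  expect_true(memb2[1, "posterior"] && memb2[2, "anterior"])
  # medial wall: below the rim plane within the cylinder
  memb3 <- acetrecon:::region_membership(rbind(c(5, 5, -30), c(5, 5, 30)),
                                         frame_t)
  expect_equal(unname(memb3[, "medial_wall"]), c(TRUE, FALSE))
})

test_that("regional volume of a bisected ball is half its volume", {
  # rotate the frame off the lattice diagonal: a sector plane lying exactly
  # on the voxel diagonal would land every tie voxel on one side
  th <- 0.3
  fr_rot <- acetabular_frame(c(0, 0, 0), 25, c(0, 0, 1),
                             c(cos(th), sin(th), 0))
  rs <- define_regions(fr_rot)
  ball <- icosphere(10, c(0, 0, 0), 4)  # centred on the hjc: sector planes
  # pass through its centre; superior wedge (90 deg) holds a quarter
  v <- regional_volume(ball, rs$superior, pitch = 0.25)
  expect_lt(abs(v - 0.25 * 4 / 3 * pi) / (0.25 * 4 / 3 * pi), 0.02)
  # ball centred on one sector boundary plane, far from the other:
  # exactly bisected
  q <- c(cos(pi / 4 + th), sin(pi / 4 + th), 0) * 30
  half <- regional_volume(icosphere(10, q, 4), rs$superior, pitch = 0.4)
  expect_lt(abs(half - 0.5 * 4 / 3 * pi) / (0.5 * 4 / 3 * pi), 0.02)
  # ball fully inside the medial cylinder keeps its own volume
  ball2 <- icosphere(10, c(0, 0, -30), 4)
  v2 <- regional_volume(ball2, rs$medial_wall, pitch = 0.4)
  # cylinder radius 21.5: ball at centre axis is fully inside laterally
  expect_lt(abs(v2 - 4 / 3 * pi) / (4 / 3 * pi), 0.02)
  # disjoint solid
  expect_equal(regional_volume(icosphere(5, c(200, 0, 0), 3), rs$superior), 0)
})

test_that("relative defect volume identities hold", {
  rs <- define_regions(frame_t)
  ball <- icosphere(8, c(0, 0, -30), 3)
  # defect = native: rdv = 100%
  expect_equal(compute_rdv(ball, ball, rs$medial_wall, pitch = 0.5), 100,
               tolerance = 1e-6)
  # no defect: 0%
  empty <- surface_mesh(matrix(numeric(0), 0, 3), matrix(integer(0), 0, 3))
  expect_equal(compute_rdv(empty, ball, rs$medial_wall, pitch = 0.5), 0)
})

test_that("half-carved medial wall gives 50% medial RDV", {
  case <- test_phantom()
  g <- acetrecon:::grid_for_meshes(case$native_mesh, 0.5, margin = 2L)
  nm <- voxelize(case$native_mesh, grid = g)
  # defect = native bone in the medial cylinder with x > 0 (half by symmetry)
  idx <- which(nm) - 1L
  i <- idx %% g$dims[1]; j <- (idx %/% g$dims[1]) %% g$dims[2]
  k <- idx %/% (g$dims[1] * g$dims[2])
  x <- g$origin[1] + (i + 0.5) * g$pitch
  y <- g$origin[2] + (j + 0.5) * g$pitch
  z <- g$origin[3] + (k + 0.5) * g$pitch
  lat <- sqrt(x^2 + y^2)
  sel <- x > 0 & lat <= 0.86 * 25 & z <= 0
  dm <- array(FALSE, g$dims); dm[which(nm)[sel]] <- TRUE
  dm <- acetrecon:::voxel_repair(acetrecon:::mask_with_grid(dm, g))
  defect <- voxel_surface(dm, g)
  rs <- define_regions(case$truth_frame)
  rdv <- compute_rdv(defect, case$native_mesh, rs$medial_wall, pitch = 0.5)
  expect_lt(abs(rdv - 50), 3)
})

test_that("defect depth follows the ray definition and is monotone", {
  # synthetic records: one ray along the polar axis
  mk_records <- function(nh, ph, iv) {
    structure(list(origin = c(0, 0, 0), directions = matrix(c(0, 0, -1), 1),
                   max_range = 62.5, native_hits = list(nh),
                   patho_hits = list(ph), intervals = list(iv),
                   valid = TRUE, point_t = list(numeric(0))),
              class = "ray_records")
  }
  # native bone from 25, crater floor at 35 (exit beyond range)
  rec <- mk_records(25, 35, matrix(c(25, 35), 1))
  dd <- compute_dd(rec, frame_t)
  expect_equal(dd$dd_mm[dd$region == "medial_wall"], 10)
  expect_equal(dd$dd_mm[dd$region == "total"], 10)
  expect_equal(dd$n_rays[dd$region == "superior"], 0L)

  # identical solids: no interval, depth zero everywhere
  rec0 <- mk_records(25, 25, matrix(numeric(0), 0, 2))
  dd0 <- compute_dd(rec0, frame_t)
  expect_true(all(dd0$dd_mm == 0))

  # deeper carve increases depth
  rec2 <- mk_records(25, 45, matrix(c(25, 45), 1))
  dd2 <- compute_dd(rec2, frame_t)
  expect_gt(dd2$dd_mm[dd2$region == "medial_wall"],
            dd$dd_mm[dd$region == "medial_wall"])
})

test_that("oracle ray-march depth matches the carved geometry on-axis", {
  # full-size phantom: the far cortex lies beyond 2.5r, so the furthest
  # in-range pathological intersection is the crater floor
  case <- make_phantom(phantom_params(), seed = 1)
  sp <- defect_spec(defect_primitive("sphere", c(0, 0, -25), 12))
  case <- carve_defect(case, sp, pitch = 0.5)
  # along the polar axis: native entry at 25 (bowl), crater floor at 37
  d <- oracle_ray_depth(case, c(0, 0, -1))
  expect_lt(abs(d - 12), 0.75)
})

test_that("metrics scale correctly under uniform scene scaling", {
  case <- test_phantom()
  sp <- defect_spec(defect_primitive("sphere", c(10, 0, -22), 10))
  case <- carve_defect(case, sp, pitch = 0.5)
  truth <- voxel_surface(truth_mask(case), case$truth_grid)
  fr <- case$truth_frame
  m1 <- regional_metrics(truth, case$native_mesh, fr, pitch = 1)
  s <- 2
  truth2 <- mesh_transform(truth, scale = s)
  native2 <- mesh_transform(case$native_mesh, scale = s)
  fr2 <- acetabular_frame(fr$hjc * s, fr$radius * s, fr$polar_axis,
                          fr$superior_axis)
  m2 <- regional_metrics(truth2, native2, fr2, pitch = 2)
  # ADV scales with the cube, RDV is invariant
  expect_equal(m2$adv_cm3, m1$adv_cm3 * s^3, tolerance = 0.05)
  expect_equal(m2$rdv_pct, m1$rdv_pct, tolerance = 0.05)
})
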