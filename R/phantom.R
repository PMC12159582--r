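#' Parametric hemipelvis phantom parameters
#'
#' The phantom is a rectangular bone block with a hemispherical acetabular cup
#' carved into one face: it preserves every geometric feature the
#' reconstruction pipeline consumes (cup cavity, rim, surrounding cortical
#' walls) while keeping analytic ground truth. The cup centre sits on the top
#' face; the cavity opens along `polar_axis`. The rim carries a small
#' saddle-height modulation (`rim_saddle`, mm), as on a real acetabulum, so
#' that rim points are not exactly coplanar (an exactly planar rim makes the
#' rim sphere fit degenerate). Rim points remain exactly on the cup sphere.
#'
#' @param block_half_extents half extents `(a, b, h)` (mm): the block spans
#'   `[-a, a] x [-b, b]` laterally and `[-2h, 0]` along the polar axis,
#'   in cup-centred coordinates.
#' @param cup_radius acetabular cup radius r (mm).
#' @param cup_centre cup centre (= true hip joint centre) in world mm.
#' @param polar_axis unit vector out of the cup (lateral).
#' @param superior_axis unit vector orthogonal to `polar_axis`.
#' @param surface_resolution target mesh edge length (mm).
#' @param rim_flare dimensionless >= 0; raises a smooth lip outside the rim.
#' @param rim_saddle rim saddle amplitude (mm); rim height varies by
#'   `-2 * rim_saddle * sin^2(phi)` around the rim.
#' @param template optional fixed ring counts (shared across a population so
#'   all meshes are corresponded); computed from the parameters when `NULL`.
#' @return an object of class `phantom_params`.
#' @export
phantom_params <- function(block_half_extents = c(75, 75, 55),
                           cup_radius = 25,
                           cup_centre = c(0, 0, 0),
                           polar_axis = c(0, 0, 1),
                           superior_axis = c(1, 0, 0),
                           surface_resolution = 2.2,
                           rim_flare = 0,
                           rim_saddle = 0.4,
                           template = NULL) {
  p <- polar_axis / sqrt(sum(polar_axis^2))
  s <- superior_axis / sqrt(sum(superior_axis^2))
  if (abs(sum(p * s)) > 1e-8) stop("polar_axis and superior_axis must be orthogonal")
  if (cup_radius <= 0) stop("cup_radius must be positive")
  if (surface_resolution <= 0) stop("surface_resolution must be positive")
  if (rim_flare < 0 || rim_saddle < 0) stop("rim_flare and rim_saddle must be >= 0")
  a <- block_half_extents[1]; b <- block_half_extents[2]; h <- block_half_extents[3]
  if (cup_radius >= 0.95 * min(a, b) || cup_radius >= 0.95 * 2 * h)
    stop("invalid parameters: cup not contained in block")
  structure(list(block_half_extents = as.numeric(block_half_extents),
                 cup_radius = cup_radius, cup_centre = as.numeric(cup_centre),
                 polar_axis = p, superior_axis = s,
                 surface_resolution = surface_resolution,
                 rim_flare = rim_flare, rim_saddle = rim_saddle,
                 template = template),
            class = "phantom_params")
}

# ring counts defining the fixed template topology
phantom_template <- function(params) {
  res <- params$surface_resolution
  r <- params$cup_radius
  a <- params$block_half_extents[1]; b <- params$block_half_extents[2]
  h <- params$block_half_extents[3]
  list(n_phi = max(24L, 2L * ceiling(pi * r / res)),
       J = max(6L, ceiling(pi * r / 2 / res)),
       K = max(4L, ceiling((min(a, b) - r) / (2 * res))),
       S = max(3L, ceiling(h / (2 * res))),
       B = max(3L, ceiling(min(a, b) / (4 * res))))
}

# face height field (local frame, cup centre at origin, polar = +z):
# saddle depression towards the rim plus optional flare lip outside the rim
phantom_face_height <- function(s, phi, params) {
  r <- params$cup_radius
  w <- params$rim_saddle
  z <- -w * (1 - cos(2 * phi)) * (s^2 / r^2) * exp(1 - s^2 / r^2)
  if (params$rim_flare > 0) {
    ramp <- pmax(0, s / r - 1)
    z <- z + params$rim_flare * r * ramp^2 * exp(-(ramp / 0.3)^2)
  }
  z
}

# lateral rim radius s_rim(phi): where the cup sphere meets the face surface
phantom_rim_radius <- function(phi, params) {
  r <- params$cup_radius
  vapply(phi, function(ph) {
    zf_at_r <- phantom_face_height(r, ph, params)
    if (abs(zf_at_r) < 1e-12) return(r)
    g <- function(s) -sqrt(pmax(r^2 - s^2, 0)) - phantom_face_height(s, ph, params)
    stats::uniroot(g, lower = r / 2, upper = r * (1 - 1e-12),
                   tol = 1e-12)$root
  }, numeric(1))
}

#' Construct a native (defect-free) phantom
#'
#' Builds the watertight, outward-oriented template mesh of the phantom and
#' wraps it in a [synthetic_case] whose pathological mesh equals the native
#' mesh (no defect). The geometry is a pure function of the parameters; the
#' seed is recorded for provenance of downstream carving.
#'
#' @param params a [phantom_params].
#' @param seed integer seed recorded in the case.
#' @return an object of class `synthetic_case`.
#' @export
make_phantom <- function(params = phantom_params(), seed = 1L) {
  tpl <- if (is.null(params$template)) phantom_template(params) else params$template
  n_phi <- tpl$n_phi
  r <- params$cup_radius
  a <- params$block_half_extents[1]; b <- params$block_half_extents[2]
  h2 <- 2 * params$block_half_extents[3]
  phi <- 2 * pi * (seq_len(n_phi) - 1) / n_phi
  s_rim <- phantom_rim_radius(phi, params)
  rect_r <- pmin(a / pmax(abs(cos(phi)), 1e-12),
                 b / pmax(abs(sin(phi)), 1e-12))

  rings <- list()
  # cup interior rings (on the sphere), pole handled separately
  th_rim <- asin(pmin(s_rim / r, 1))
  for (j in seq_len(tpl$J)) {
    th <- th_rim * j / tpl$J
    s <- r * sin(th)
    rings[[length(rings) + 1L]] <- cbind(s * cos(phi), s * sin(phi),
                                         -sqrt(pmax(r^2 - s^2, 0)))
  }
  # face rings from rim to block edge (rim ring itself is cup ring J)
  for (m in seq_len(tpl$K)) {
    s <- s_rim + (rect_r - s_rim) * m / tpl$K
    rings[[length(rings) + 1L]] <- cbind(s * cos(phi), s * sin(phi),
                                         phantom_face_height(s, phi, params))
  }
  z_edge <- phantom_face_height(rect_r, phi, params)
  # side rings down the walls
  for (t in seq_len(tpl$S)) {
    z <- z_edge + (-h2 - z_edge) * t / tpl$S
    rings[[length(rings) + 1L]] <- cbind(rect_r * cos(phi), rect_r * sin(phi), z)
  }
  # bottom rings collapsing to the bottom pole
  for (u in seq_len(tpl$B - 1L)) {
    s <- rect_r * (1 - u / tpl$B)
    rings[[length(rings) + 1L]] <- cbind(s * cos(phi), s * sin(phi), -h2)
  }

  nring <- length(rings)
  v <- rbind(c(0, 0, -r), do.call(rbind, rings), c(0, 0, -h2))
  ring_idx <- function(i) 1L + (i - 1L) * n_phi + seq_len(n_phi)
  nxt <- c(seq_len(n_phi)[-1], 1L)
  f <- list()
  f[[1]] <- cbind(1L, ring_idx(1L), ring_idx(1L)[nxt])           # top pole fan
  for (i in seq_len(nring - 1L)) {
    r1 <- ring_idx(i); r2 <- ring_idx(i + 1L)
    f[[length(f) + 1L]] <- rbind(cbind(r1, r2, r2[nxt]),
                                 cbind(r1, r2[nxt], r1[nxt]))
  }
  last <- ring_idx(nring)
  bp <- nrow(v)
  f[[length(f) + 1L]] <- cbind(bp, last[nxt], last)               # bottom pole fan
  faces <- do.call(rbind, f)

  mesh <- surface_mesh(v, faces)
  if (mesh_volume(mesh) < 0) mesh <- surface_mesh(v, faces[, c(1, 3, 2)])

  # local -> world: +x -> superior, +z -> polar, +y -> polar x superior
  p_ax <- params$polar_axis; s_ax <- params$superior_axis
  y_ax <- c(p_ax[2] * s_ax[3] - p_ax[3] * s_ax[2],
            p_ax[3] * s_ax[1] - p_ax[1] * s_ax[3],
            p_ax[1] * s_ax[2] - p_ax[2] * s_ax[1])
  Rg <- cbind(s_ax, y_ax, p_ax)
  mesh <- mesh_transform(mesh, rotation = Rg, translation = params$cup_centre)

  frame <- acetabular_frame(hjc = params$cup_centre, radius = r,
                            polar_axis = p_ax, superior_axis = s_ax)
  structure(list(native_mesh = mesh, pathological_mesh = mesh,
                 truth_defect_indices = NULL, truth_grid = NULL,
                 truth_defect_volume = 0, truth_frame = frame,
                 truth_regional = NULL, params = params, seed = as.integer(seed),
                 defect_spec = defect_spec()),
            class = "synthetic_case")
}

#' @export
print.synthetic_case <- function(x, ...) {
  cat(sprintf("synthetic_case (seed %d): cup radius %.1f mm\n",
              x$seed, x$params$cup_radius))
  cat(sprintf("  native: %d vertices; defect truth volume %.2f cm^3 (%d primitives)\n",
              nrow(x$native_mesh$vertices), x$truth_defect_volume / 1000,
              length(x$defect_spec$primitives)))
  invisible(x)
}

#' Defect specification: union of carving primitives
#'
#' @param ... primitives created by [defect_primitive()].
#' @export
defect_spec <- function(...) {
  prims <- list(...)
  if (length(prims) == 1L && is.list(prims[[1]]) &&
      !inherits(prims[[1]], "defect_primitive")) prims <- prims[[1]]
  stopifnot(all(vapply(prims, inherits, logical(1), "defect_primitive")))
  structure(list(primitives = prims), class = "defect_spec")
}

#' A spherical or ellipsoidal carving primitive
#'
#' @param shape "sphere" or "ellipsoid".
#' @param centre centre (mm).
#' @param semi_axes radius (sphere) or length-3 semi-axes (ellipsoid), mm.
#' @param orientation 3x3 rotation mapping ellipsoid axes to world; identity
#'   by default.
#' @export
defect_primitive <- function(shape = c("sphere", "ellipsoid"), centre,
                             semi_axes, orientation = diag(3)) {
  shape <- match.arg(shape)
  semi_axes <- as.numeric(semi_axes)
  if (shape == "sphere") semi_axes <- rep(semi_axes[1], 3)
  if (length(semi_axes) != 3L || any(semi_axes <= 0))
    stop("semi_axes must be positive")
  structure(list(shape = shape, centre = as.numeric(centre),
                 semi_axes = semi_axes, orientation = orientation),
            class = "defect_primitive")
}

# indices of grid voxels whose centre lies inside the primitive
primitive_voxels <- function(grid, prim) {
  e <- prim$semi_axes
  rmax <- max(e)
  lo <- prim$centre - rmax - grid$pitch
  hi <- prim$centre + rmax + grid$pitch
  i0 <- pmax(ceiling((lo - grid$origin) / grid$pitch - 0.5) + 1L, 1L)
  i1 <- pmin(floor((hi - grid$origin) / grid$pitch - 0.5) + 1L, grid$dims)
  if (any(i0 > i1)) return(integer(0))
  xs <- grid$origin[1] + (seq(i0[1], i1[1]) - 0.5) * grid$pitch
  ys <- grid$origin[2] + (seq(i0[2], i1[2]) - 0.5) * grid$pitch
  zs <- grid$origin[3] + (seq(i0[3], i1[3]) - 0.5) * grid$pitch
  gx <- rep(xs, times = length(ys) * length(zs))
  gy <- rep(rep(ys, each = length(xs)), times = length(zs))
  gz <- rep(zs, each = length(xs) * length(ys))
  d <- cbind(gx - prim$centre[1], gy - prim$centre[2], gz - prim$centre[3])
  loc <- d %*% prim$orientation          # world -> primitive axes
  inside <- (loc[, 1] / e[1])^2 + (loc[, 2] / e[2])^2 + (loc[, 3] / e[3])^2 <= 1
  if (!any(inside)) return(integer(0))
  ii <- rep(seq(i0[1], i1[1]), times = length(ys) * length(zs))
  jj <- rep(rep(seq(i0[2], i1[2]), each = length(xs)), times = length(zs))
  kk <- rep(seq(i0[3], i1[3]), each = length(xs) * length(ys))
  (ii[inside] - 1L) + grid$dims[1] * ((jj[inside] - 1L) +
    grid$dims[2] * (kk[inside] - 1L)) + 1L
}

#' Carve a defect into a synthetic case
#'
#' The native solid is voxelized at `pitch`; the union of the primitives is
#' evaluated analytically per voxel centre; the pathological solid is the
#' native solid minus that union, surfaced as a watertight mesh. The ground
#' truth defect mask (native AND primitives) and its volume are recorded,
#' together with regional truth metrics against the true frame.
#'
#' @param case a [synthetic_case] with a native mesh.
#' @param spec a [defect_spec].
#' @param pitch voxel pitch (mm).
#' @return the updated `synthetic_case`.
#' @export
carve_defect <- function(case, spec, pitch = 0.5) {
  stopifnot(inherits(case, "synthetic_case"), inherits(spec, "defect_spec"),
            pitch > 0)
  if (length(spec$primitives) == 0L) {
    case$pathological_mesh <- case$native_mesh
    case$truth_defect_volume <- 0
    case$defect_spec <- spec
    return(case)
  }
  grid <- grid_for_meshes(case$native_mesh, pitch, margin = 3L)
  native_mask <- voxelize(case$native_mesh, grid = grid, name = "native_mesh")
  region <- logical(length(native_mask))
  kept <- list()
  for (prim in spec$primitives) {
    idx <- primitive_voxels(grid, prim)
    if (length(idx) == 0L || !any(native_mask[idx])) {
      warning("defect primitive does not overlap the native solid; dropped")
      next
    }
    region[idx] <- TRUE
    kept[[length(kept) + 1L]] <- prim
  }
  truth <- voxel_repair(mask_with_grid(native_mask & array(region, grid$dims),
                                       grid))
  patho_mask <- voxel_repair(mask_with_grid(native_mask & !truth, grid))
  case$pathological_mesh <- voxel_surface(patho_mask, grid)
  # store the truth mask sparsely (cases are carried around in batches)
  case$truth_defect_indices <- which(truth)
  case$truth_grid <- grid
  case$truth_defect_volume <- sum(truth) * pitch^3
  case$defect_spec <- defect_spec(kept)
  case$truth_regional <- truth_regional_metrics(truth, native_mask, grid,
                                                case$truth_frame)
  case
}

#' Ground-truth defect mask of a carved case
#'
#' Reconstructs the dense logical voxel mask (with its `grid` attribute) from
#' the sparsely stored ground truth.
#'
#' @param case a carved [synthetic_case].
#' @export
truth_mask <- function(case) {
  if (is.null(case$truth_defect_indices))
    stop("case has no carved defect")
  m <- array(FALSE, case$truth_grid$dims)
  m[case$truth_defect_indices] <- TRUE
  mask_with_grid(m, case$truth_grid)
}

# counts of mask voxels per region (C++ single pass); returns cm^3
region_mask_volumes <- function(mask, grid, frame,
                                factors = c(superior = 2.2, anterior = 1.9,
                                            posterior = 1.9, medial_wall = 0.86),
                                medial_length_factor = 2.5,
                                ball_factor = 2.5) {
  cnt <- cpp_region_counts(as.logical(mask), grid$dims, grid$origin,
                           grid$pitch, frame$hjc, frame$superior_axis,
                           frame$anterior_axis, frame$polar_axis,
                           frame$radius, unname(factors[c("superior",
                                                          "anterior",
                                                          "posterior",
                                                          "medial_wall")]),
                           medial_length_factor, ball_factor)
  cnt * grid$pitch^3 / 1000
}

# regional truth ADV/RDV from voxel masks and the true frame (analytic
# membership; DD is per-ray and supplied by oracle_ray_depth on demand)
truth_regional_metrics <- function(truth, native_mask, grid, frame,
                                   factors = c(superior = 2.2, anterior = 1.9,
                                               posterior = 1.9, medial_wall = 0.86)) {
  v_t <- region_mask_volumes(truth, grid, frame, factors)
  v_n <- region_mask_volumes(native_mask & !truth, grid, frame, factors)
  regions <- c("superior", "anterior", "posterior", "medial_wall")
  adv <- v_t[regions]
  nat <- v_n[regions] + adv
  v3 <- grid$pitch^3 / 1000
  tot_adv <- sum(truth) * v3
  tot_nat <- v_n[["ball"]] + v_t[["ball"]]
  data.frame(region = c(regions, "total"),
             adv_cm3 = unname(c(adv, tot_adv)),
             native_cm3 = unname(c(nat, tot_nat)),
             rdv_pct = unname(c(100 * adv / pmax(nat, 1e-12),
                                100 * v_t[["ball"]] / max(tot_nat, 1e-12))),
             dd_mm = NA_real_, n_rays = NA_integer_,
             row.names = NULL)
}

#' Sample a corresponded training population of native phantoms
#'
#' Draws phantom parameters from a population model with a common allometric
#' scale factor (block extents and cup radius co-vary, with a small
#' independent cup-radius jitter) plus independent rim-saddle variation. All
#' meshes share one template parametrization and are therefore corresponded
#' vertex-for-vertex.
#'
#' @param n number of members.
#' @param param_distribution a [population_model].
#' @param seed integer seed.
#' @return list of [surface_mesh] with a `params` data.frame attribute.
#' @export
sample_population <- function(n, param_distribution = population_model(),
                              seed = 1L) {
  stopifnot(n >= 0)
  pm <- param_distribution
  ref <- phantom_params(block_half_extents = pm$block_half_extents,
                        cup_radius = pm$cup_radius,
                        surface_resolution = pm$surface_resolution,
                        rim_saddle = pm$rim_saddle)
  tpl <- phantom_template(ref)
  meshes <- vector("list", n)
  log <- vector("list", n)
  with_seed(seed, {
    for (i in seq_len(n)) {
      prm <- draw_phantom_params(pm, template = tpl)
      meshes[[i]] <- make_phantom(prm, seed = seed + i)$native_mesh
      p <- prm$block_half_extents
      log[[i]] <- data.frame(a = p[1], b = p[2], h = p[3],
                             cup_radius = prm$cup_radius,
                             rim_saddle = prm$rim_saddle)
    }
  })
  attr(meshes, "params") <- if (n > 0) do.call(rbind, log) else NULL
  meshes
}

#' Population model for the synthetic training anatomy
#'
#' Defaults emulate adult inter-subject variation: a 6% SD overall size factor
#' (pelvis and acetabulum scale together), 2% SD independent jitter per
#' dimension (so the cup radius is predictable from, but not determined by,
#' the surrounding bone), and rim-saddle variation. The reference block
#' (150 x 150 x 110 mm around a 25 mm cup) keeps bone beyond the 2.5r
#' excision ball in every direction except the periacetabular face, as a
#' hemipelvis does around the acetabulum.
#'
#' @param block_half_extents,cup_radius,rim_saddle reference phantom shape.
#' @param scale_sd SD of the shared allometric scale factor.
#' @param jitter_sd SD of the per-dimension relative jitter.
#' @param saddle_sd,saddle_min rim-saddle variation (mm).
#' @param surface_resolution template target edge length (mm).
#' @export
population_model <- function(block_half_extents = c(75, 75, 55),
                             cup_radius = 25, rim_saddle = 0.4,
                             scale_sd = 0.06, jitter_sd = 0.02,
                             saddle_sd = 0.08, saddle_min = 0.15,
                             surface_resolution = 2.2) {
  list(block_half_extents = block_half_extents, cup_radius = cup_radius,
       rim_saddle = rim_saddle, scale_sd = scale_sd, jitter_sd = jitter_sd,
       saddle_sd = saddle_sd, saddle_min = saddle_min,
       surface_resolution = surface_resolution)
}

#' Draw one set of phantom parameters from a population model
#'
#' Uses the current RNG stream (wrap in a seeded context for reproducibility);
#' invalid draws (cup not contained in the block) are rejected and resampled.
#'
#' @param param_distribution a [population_model].
#' @param template optional fixed template ring counts.
#' @export
draw_phantom_params <- function(param_distribution = population_model(),
                                template = NULL) {
  pm <- param_distribution
  repeat {
    g <- stats::rnorm(1, 1, pm$scale_sd)
    jit <- stats::rnorm(4, 0, pm$jitter_sd)
    a <- pm$block_half_extents[1] * g * (1 + jit[1])
    b <- pm$block_half_extents[2] * g * (1 + jit[2])
    h <- pm$block_half_extents[3] * g * (1 + jit[3])
    r <- pm$cup_radius * g * (1 + jit[4])
    w <- max(pm$saddle_min, stats::rnorm(1, pm$rim_saddle, pm$saddle_sd))
    if (r > 0 && r < 0.95 * min(a, b) && r < 0.95 * 2 * h)
      return(phantom_params(block_half_extents = c(a, b, h), cup_radius = r,
                            surface_resolution = pm$surface_resolution,
                            rim_saddle = w, template = template))
  }
}

#' Brute-force voxel oracle for solid volumes and Booleans
#'
#' Test-side ground truth, independent of the pipeline's Boolean engine:
#' inside/outside is decided per voxel centre by crossing parity along the
#' x axis (the pipeline voxelizes along z), and volume is the voxel count
#' times `pitch^3` (the pipeline reports divergence-theorem mesh volumes).
#'
#' @param meshA a watertight [surface_mesh].
#' @param meshB second mesh for Boolean ops; `NULL` for `op = "volume"`.
#' @param op one of "volume", "difference", "intersection", "union".
#' @param pitch voxel pitch (mm).
#' @return list with `mask` (logical array with `grid` attr) and `volume` mm^3.
#' @export
voxel_oracle <- function(meshA, meshB = NULL,
                         op = c("volume", "difference", "intersection", "union"),
                         pitch = 0.5) {
  op <- match.arg(op)
  stopifnot(pitch > 0)
  if (!mesh_is_watertight(meshA)) stop("mesh is not watertight: meshA")
  if (op != "volume" && is.null(meshB)) stop("meshB required for op ", op)
  meshes <- if (is.null(meshB)) list(meshA) else list(meshA, meshB)
  grid <- grid_for_meshes(meshes, pitch, margin = 2L)
  vox <- function(m, nm) {
    if (!mesh_is_watertight(m)) stop("mesh is not watertight: ", nm)
    cpp_voxelize(m$vertices, m$faces, grid$origin, grid$dims, grid$pitch, 0L)
  }
  ma <- vox(meshA, "meshA")
  mask <- if (op == "volume") ma else {
    mb <- vox(meshB, "meshB")
    switch(op, difference = ma & !mb, intersection = ma & mb, union = ma | mb)
  }
  mask <- mask_with_grid(array(mask, grid$dims), grid)
  list(mask = mask, volume = sum(mask) * pitch^3)
}

#' Oracle ray-marched defect depth along one direction
#'
#' Marches the truth voxel masks from the hip joint centre and reports the
#' distance from the furthest pathological-bone boundary within range to the
#' first native-bone entry, floored at zero - the voxel-level analogue of the
#' ray depth definition used by the pipeline.
#'
#' @param case a carved [synthetic_case].
#' @param direction unit direction.
#' @param max_range range cutoff (mm); defaults to 2.5x the cup radius.
#' @export
oracle_ray_depth <- function(case, direction,
                             max_range = 2.5 * case$truth_frame$radius) {
  stopifnot(!is.null(case$truth_defect_indices))
  grid <- case$truth_grid
  truth <- truth_mask(case)
  native_m <- attr_native_mask(case)
  d <- direction / sqrt(sum(direction^2))
  ts <- seq(grid$pitch / 4, max_range, by = grid$pitch / 2)
  pts <- sweep(outer(ts, d), 2, case$truth_frame$hjc, "+")
  at <- function(mask) {
    ijk <- floor(sweep(pts, 2, grid$origin) / grid$pitch) + 1L
    ok <- ijk[, 1] >= 1 & ijk[, 2] >= 1 & ijk[, 3] >= 1 &
      ijk[, 1] <= grid$dims[1] & ijk[, 2] <= grid$dims[2] & ijk[, 3] <= grid$dims[3]
    v <- logical(length(ts))
    v[ok] <- mask[cbind(ijk[ok, 1], ijk[ok, 2], ijk[ok, 3])]
    v
  }
  native <- at(truth) | at(native_m)
  patho <- at(native_m) & !at(truth)
  if (!any(native)) return(0)
  t_n <- ts[which(native)[1]]
  trans <- which(diff(c(FALSE, patho)) != 0)
  if (length(trans) == 0L) return(0)
  t_p <- ts[max(trans)]
  max(t_p - t_n, 0)
}

# native mask re-voxelized on the truth grid
attr_native_mask <- function(case) {
  voxelize(case$native_mesh, grid = case$truth_grid, check = FALSE)
}

# evaluate code with a temporary RNG seed, restoring global state afterwards
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  code
}
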