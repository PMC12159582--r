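#' Anatomical acetabular regions
#'
#' Four regions about the hip joint centre: superior, anterior and posterior
#' angular sectors (dominant-axis rule: a point belongs to the sector of the
#' in-plane axis along which its component is largest and positive) truncated
#' at 2.2r (superior) and 1.9r (anterior/posterior), and a medial-wall
#' cylinder of radius 0.86r aligned with the polar axis, extending 2.5r
#' medially from the hip joint centre. Regions may overlap; no partition is
#' implied.
#'
#' @param frame an [acetabular_frame].
#' @param factors named radial factors (defaults 2.2, 1.9, 1.9, 0.86).
#' @param medial_length_factor medial extent of the cylinder in cup radii.
#' @return an object of class `region_set`: watertight solids `superior`,
#'   `anterior`, `posterior`, `medial_wall` plus the frame and factors.
#' @export
define_regions <- function(frame,
                           factors = c(superior = 2.2, anterior = 1.9,
                                       posterior = 1.9, medial_wall = 0.86),
                           medial_length_factor = 2.5) {
  r <- frame$radius
  sup <- wedge_solid(frame$hjc, factors[["superior"]] * r,
                     frame$superior_axis, frame$anterior_axis,
                     frame$polar_axis)
  ant <- wedge_solid(frame$hjc, factors[["anterior"]] * r,
                     frame$anterior_axis, frame$superior_axis,
                     frame$polar_axis)
  post <- wedge_solid(frame$hjc, factors[["posterior"]] * r,
                      -frame$anterior_axis, frame$superior_axis,
                      frame$polar_axis)
  med <- cylinder_mesh(radius = factors[["medial_wall"]] * r,
                       base = frame$hjc, axis = -frame$polar_axis,
                       length = medial_length_factor * r)
  structure(list(superior = sup, anterior = ant, posterior = post,
                 medial_wall = med, frame = frame, factors = factors,
                 medial_length_factor = medial_length_factor),
            class = "region_set")
}

# spherical wedge solid: { rho * d : rho <= R, d.D >= |d.O| }, where the two
# bounding planes intersect along the polar axis P; built as a spherical lune
# patch plus two flat half-disc fans, all sharing the apex vertices +/- R*P
wedge_solid <- function(centre, R, D, O, P, n_mu = 48L, n_t = 16L) {
  D <- D / sqrt(sum(D^2)); O <- O / sqrt(sum(O^2)); P <- P / sqrt(sum(P^2))
  mu <- pi * seq_len(n_mu - 1L) / n_mu            # interior arc stations
  th <- pi / 4 * seq(-1, 1, length.out = n_t + 1L)
  e <- function(t_) outer(cos(t_), D) + outer(sin(t_), O)
  # vertex layout: apex+ (1), apex- (2), centre (3), grid rows by mu
  verts <- rbind(centre + R * P, centre - R * P, centre)
  grid_idx <- matrix(0L, n_mu - 1L, n_t + 1L)
  for (i in seq_along(mu)) {
    ring <- cos(mu[i]) * matrix(P, n_t + 1L, 3, byrow = TRUE) +
      sin(mu[i]) * e(th)
    grid_idx[i, ] <- nrow(verts) + seq_len(n_t + 1L)
    verts <- rbind(verts, sweep(R * ring, 2, centre, "+"))
  }
  faces <- list()
  add <- function(a, b, c_) faces[[length(faces) + 1L]] <<- c(a, b, c_)
  # spherical patch
  for (j in seq_len(n_t)) {
    add(1L, grid_idx[1, j], grid_idx[1, j + 1])
    add(2L, grid_idx[n_mu - 1L, j + 1], grid_idx[n_mu - 1L, j])
  }
  for (i in seq_len(n_mu - 2L))
    for (j in seq_len(n_t)) {
      a <- grid_idx[i, j]; b <- grid_idx[i, j + 1]
      c_ <- grid_idx[i + 1L, j + 1]; d <- grid_idx[i + 1L, j]
      add(a, b, c_); add(a, c_, d)
    }
  # flat side fans (boundary arcs at th = +/- pi/4), closed through the apexes
  side1 <- c(1L, grid_idx[, n_t + 1L], 2L)
  side2 <- c(1L, grid_idx[, 1L], 2L)
  for (i in seq_len(length(side1) - 1L)) add(3L, side1[i + 1L], side1[i])
  for (i in seq_len(length(side2) - 1L)) add(3L, side2[i], side2[i + 1L])
  F <- do.call(rbind, faces)
  mesh <- surface_mesh(verts, F)
  # orient each face outward (radial for the patch, away from the interior
  # for the fans), then the mesh is globally consistent
  fn <- face_normals(mesh)
  ctrs <- (mesh$vertices[F[, 1], ] + mesh$vertices[F[, 2], ] +
             mesh$vertices[F[, 3], ]) / 3
  interior <- centre + R / 4 * D
  outward <- ctrs - matrix(interior, nrow(F), 3, byrow = TRUE)
  flip <- rowSums(fn$normals * outward) < 0
  F[flip, ] <- F[flip, c(1, 3, 2)]
  mesh <- surface_mesh(verts, F)
  if (mesh_volume(mesh) < 0) mesh <- surface_mesh(verts, F[, c(1, 3, 2)])
  mesh
}

# membership of points in the four regions (analytic, no meshes): columns
# superior/anterior/posterior/medial_wall
region_membership <- function(points, frame,
                              factors = c(superior = 2.2, anterior = 1.9,
                                          posterior = 1.9, medial_wall = 0.86),
                              medial_length_factor = 2.5) {
  rel <- sweep(as.matrix(points), 2, frame$hjc)
  su <- rel %*% frame$superior_axis
  an <- rel %*% frame$anterior_axis
  po <- rel %*% frame$polar_axis
  rho <- sqrt(rowSums(rel^2))
  r <- frame$radius
  lat <- sqrt(pmax(rho^2 - po^2, 0))
  cbind(superior = as.vector(su >= abs(an) & su > 0 &
                               rho <= factors[["superior"]] * r),
        anterior = as.vector(an >= abs(su) & an > 0 &
                               rho <= factors[["anterior"]] * r),
        posterior = as.vector(-an >= abs(su) & an < 0 &
                                rho <= factors[["posterior"]] * r),
        medial_wall = as.vector(lat <= factors[["medial_wall"]] * r &
                                  po <= 0 &
                                  po >= -medial_length_factor * r))
}

#' Volume of a solid inside a region (cm^3)
#'
#' Boolean intersection on a shared voxel grid. The volume is the voxel
#' count times `pitch^3` of the raw intersection mask (equivalently, the
#' divergence-theorem volume of its unrepaired boundary surface): voxel
#' centre sampling of an intersection is unbiased, whereas the manifold
#' repair applied before surfacing inflates solids bounded by 45-degree
#' planes, as region sectors are.
#'
#' @param solid,region watertight [surface_mesh] solids.
#' @param pitch voxel pitch (mm).
#' @export
regional_volume <- function(solid, region, pitch = 0.5) {
  if (nrow(solid$faces) == 0L) return(0)
  bb_s <- mesh_bbox(solid); bb_r <- mesh_bbox(region)
  if (any(bb_s$lo > bb_r$hi) || any(bb_s$hi < bb_r$lo)) return(0)
  grid <- grid_for_meshes(list(solid, region), pitch)
  ma <- voxelize(solid, grid = grid, name = "solid")
  mb <- voxelize(region, grid = grid, name = "region")
  sum(ma & mb) * pitch^3 / 1000
}

#' Relative defect volume in a region (percent)
#'
#' `100 * vol(defect in region) / vol(native reference in region)` where the
#' native reference is the union of the native estimate and the defect solid
#' (the estimated bone stock before loss).
#'
#' @param defect defect solid ([surface_mesh]).
#' @param native_solid native (defect-free) estimate.
#' @param region region solid.
#' @param pitch voxel pitch (mm).
#' @export
compute_rdv <- function(defect, native_solid, region, pitch = 0.5) {
  empty_defect <- nrow(defect$faces) == 0L
  meshes <- if (empty_defect) list(region, native_solid)
            else list(region, defect, native_solid)
  grid <- grid_for_meshes(meshes, pitch)
  mr <- voxelize(region, grid = grid, check = FALSE)
  md <- if (!empty_defect)
    voxelize(defect, grid = grid, check = FALSE) else array(FALSE, grid$dims)
  mn <- voxelize(native_solid, grid = grid, check = FALSE)
  denom <- sum((mn | md) & mr)
  if (denom == 0) return(NA_real_)
  100 * sum(md & mr) / denom
}

#' Regional defect depths from ray records (mm)
#'
#' Along every valid ray with a defect interval, depth is the distance from
#' the furthest valid pathological intersection within range to the first
#' native intersection, floored at zero. A ray is assigned to the region(s)
#' containing its defect-interval midpoints; regional depth is the mean over
#' assigned rays with positive depth.
#'
#' @param records ray records from [reconstruct_defect()].
#' @param frame an [acetabular_frame].
#' @param factors,medial_length_factor region geometry (see [define_regions]).
#' @return data.frame with `region`, `dd_mm`, `n_rays`.
#' @export
compute_dd <- function(records, frame,
                       factors = c(superior = 2.2, anterior = 1.9,
                                   posterior = 1.9, medial_wall = 0.86),
                       medial_length_factor = 2.5) {
  regions <- c("superior", "anterior", "posterior", "medial_wall")
  depth_by_region <- stats::setNames(rep(list(numeric(0)), 5),
                                     c(regions, "total"))
  n <- nrow(records$directions)
  for (i in seq_len(n)) {
    if (!records$valid[i]) next
    iv <- records$intervals[[i]]
    if (nrow(iv) == 0L) next
    nh <- records$native_hits[[i]]
    ph <- records$patho_hits[[i]]
    if (length(nh) == 0L) next
    t_far <- if (length(ph) > 0) max(ph) else max(iv[, 2])
    depth <- max(t_far - nh[1], 0)
    if (depth <= 0) next
    mids <- (iv[, 1] + iv[, 2]) / 2
    pts <- sweep(outer(mids, records$directions[i, ]), 2, records$origin, "+")
    memb <- region_membership(pts, frame, factors, medial_length_factor)
    hit_regions <- regions[colSums(memb) > 0]
    for (rg in hit_regions)
      depth_by_region[[rg]] <- c(depth_by_region[[rg]], depth)
    depth_by_region[["total"]] <- c(depth_by_region[["total"]], depth)
  }
  data.frame(region = names(depth_by_region),
             dd_mm = vapply(depth_by_region,
                            function(d) if (length(d)) mean(d) else 0,
                            numeric(1)),
             n_rays = vapply(depth_by_region, length, integer(1)),
             row.names = NULL)
}

#' Regional defect metrics (ADV, RDV, DD)
#'
#' Per region and in total: absolute defect volume (cm^3), relative defect
#' volume (% of the regional native reference = native estimate plus defect),
#' and mean defect depth (mm). Volumes are computed by voxel membership on a
#' shared grid with analytic region geometry; the total row uses the excision
#' ball (2.5r) as its native reference neighbourhood.
#'
#' @param defect_model a [defect_model] (or defect [surface_mesh]).
#' @param native_mesh native estimate [surface_mesh].
#' @param frame an [acetabular_frame].
#' @param records ray records for depth; `NULL` leaves DD as `NA`.
#' @param pitch voxel pitch (mm).
#' @param factors,medial_length_factor region geometry.
#' @return data.frame of class `regional_metrics`.
#' @export
regional_metrics <- function(defect_model, native_mesh, frame, records = NULL,
                             pitch = 0.5,
                             factors = c(superior = 2.2, anterior = 1.9,
                                         posterior = 1.9, medial_wall = 0.86),
                             medial_length_factor = 2.5) {
  defect <- if (inherits(defect_model, "defect_model")) defect_model$mesh
            else defect_model
  ball <- excision_sphere(frame, factor = 2.5, subdivisions = 3L)
  # all regions live inside the excision ball, so the grid need not cover
  # bone far from the acetabulum
  has_defect <- nrow(defect$faces) > 0
  meshes <- if (has_defect) list(ball, defect) else list(ball)
  grid <- grid_for_meshes(meshes, pitch)
  mn <- voxelize(native_mesh, grid = grid, check = FALSE)
  md <- if (has_defect) voxelize(defect, grid = grid, check = FALSE)
        else array(FALSE, grid$dims)
  v_d <- region_mask_volumes(md, grid, frame, factors, medial_length_factor)
  v_n <- region_mask_volumes(mn | md, grid, frame, factors,
                             medial_length_factor)
  regions <- c("superior", "anterior", "posterior", "medial_wall")
  adv <- v_d[regions]
  nat <- v_n[regions]
  tot_adv <- if (has_defect)
    (if (inherits(defect_model, "defect_model")) defect_model$volume
     else mesh_volume(defect) / 1000) else 0
  tot_nat <- v_n[["ball"]]
  dd <- if (!is.null(records)) compute_dd(records, frame, factors,
                                          medial_length_factor)
        else data.frame(region = c(regions, "total"), dd_mm = NA_real_,
                        n_rays = NA_integer_)
  out <- data.frame(region = c(regions, "total"),
                    adv_cm3 = unname(c(adv, tot_adv)),
                    native_cm3 = unname(c(nat, tot_nat)),
                    rdv_pct = unname(c(100 * adv / pmax(nat, 1e-12),
                                       100 * v_d[["ball"]] /
                                         max(tot_nat, 1e-12))),
                    row.names = NULL)
  out <- merge(out, dd, by = "region", sort = FALSE)
  out <- out[match(c("superior", "anterior", "posterior", "medial_wall",
                     "total"), out$region), ]
  rownames(out) <- NULL
  class(out) <- c("regional_metrics", "data.frame")
  out
}

#' @export
print.regional_metrics <- function(x, ...) {
  cat("Regional defect metrics (ADV cm^3, RDV %, DD mm):\n")
  df <- as.data.frame(x)
  df$adv_cm3 <- round(df$adv_cm3, 2)
  df$native_cm3 <- round(df$native_cm3, 2)
  df$rdv_pct <- round(df$rdv_pct, 1)
  df$dd_mm <- round(df$dd_mm, 2)
  print(df, row.names = FALSE)
  invisible(x)
}
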