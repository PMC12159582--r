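#' Spherical ray set from the hip joint centre
#'
#' Near-uniform direction set over the full sphere (Fibonacci lattice) whose
#' mean nearest-neighbour angle approximates `angular_spacing`. Uniform
#' solid-angle coverage avoids polar oversampling, which would bias defect
#' point density and the downstream cluster-size filter.
#'
#' @param frame an [acetabular_frame]; rays originate at the hip joint centre.
#' @param angular_spacing degrees, in (0.1, 10].
#' @param max_range range cutoff (mm), by default 2.5x the acetabular radius.
#' @return an object of class `ray_set` with unit `directions`.
#' @export
generate_rays <- function(frame, angular_spacing = 1,
                          max_range = 2.5 * frame$radius) {
  if (angular_spacing <= 0.1 || angular_spacing > 10)
    stop("angular_spacing must be in (0.1, 10] degrees")
  # one direction per spacing^2 square degrees of the full sphere
  n <- round(4 * pi * (180 / pi)^2 / angular_spacing^2)
  i <- seq_len(n) - 1
  z <- 1 - (2 * i + 1) / n
  phi <- i * pi * (3 - sqrt(5))
  s <- sqrt(pmax(1 - z^2, 0))
  dirs <- cbind(s * cos(phi), s * sin(phi), z)
  structure(list(origin = frame$hjc, directions = dirs,
                 angular_spacing = angular_spacing, max_range = max_range),
            class = "ray_set")
}

#' @export
print.ray_set <- function(x, ...) {
  cat(sprintf("ray_set: %d directions at %.2f deg spacing, range %.1f mm\n",
              nrow(x$directions), x$angular_spacing, x$max_range))
  invisible(x)
}

#' Cast a single ray against a mesh
#'
#' Returns the first `max_hits` intersection distances with `t > 0`,
#' ascending, truncated at `max_range`; grazing duplicates within 1e-6 mm are
#' merged. `truncated` records whether further in-range intersections beyond
#' `max_hits` existed.
#'
#' @param origin ray origin (mm).
#' @param direction unit direction.
#' @param mesh a [surface_mesh].
#' @param max_hits intersection cap (4).
#' @param max_range range cutoff (mm).
#' @return list with `hits` (numeric) and `truncated` (logical).
#' @export
cast_ray <- function(origin, direction, mesh, max_hits = 4L, max_range = Inf) {
  d <- direction / sqrt(sum(direction^2))
  res <- cpp_ray_cast(mesh$vertices, mesh$faces, matrix(origin, 1),
                      matrix(d, 1), if (is.finite(max_range)) max_range else 1e12)
  hits <- res$t
  list(hits = utils::head(hits, max_hits),
       truncated = length(hits) > max_hits)
}

# bulk casting: all rays of a ray_set against one mesh -> list of hit vectors
# plus a truncation flag vector
cast_ray_set <- function(rays, mesh, max_hits = 4L) {
  res <- cpp_ray_cast(mesh$vertices, mesh$faces, matrix(rays$origin, 1),
                      rays$directions, rays$max_range)
  n <- nrow(rays$directions)
  hits <- vector("list", n)
  if (length(res$ray) > 0) {
    sp <- split(res$t, factor(res$ray, levels = seq_len(n)))
    hits <- unname(sp)
  } else {
    hits <- rep(list(numeric(0)), n)
  }
  truncated <- lengths(hits) > max_hits
  hits <- lapply(hits, utils::head, max_hits)
  list(hits = hits, truncated = truncated)
}

# inside-intervals of a solid along a ray given its (<= max_hits) hit list;
# the origin is assumed outside the solid (inside the cup cavity), so odd
# hit counts mean the solid extends beyond max_range and the last interval
# closes there
hit_intervals <- function(hits, max_range) {
  if (length(hits) == 0L) return(matrix(numeric(0), 0, 2))
  h <- hits
  if (length(h) %% 2L == 1L) h <- c(h, max_range)
  matrix(h, ncol = 2, byrow = TRUE)
}

# interval set difference A \ B (rows are disjoint ascending intervals)
interval_diff <- function(A, B) {
  if (nrow(A) == 0L) return(A)
  out <- list()
  for (i in seq_len(nrow(A))) {
    segs <- matrix(A[i, ], 1)
    for (j in seq_len(nrow(B))) {
      if (nrow(segs) == 0L) break
      nxt <- list()
      for (k in seq_len(nrow(segs))) {
        s0 <- segs[k, 1]; s1 <- segs[k, 2]
        b0 <- B[j, 1]; b1 <- B[j, 2]
        if (b1 <= s0 || b0 >= s1) {
          nxt[[length(nxt) + 1L]] <- c(s0, s1)
        } else {
          if (b0 > s0) nxt[[length(nxt) + 1L]] <- c(s0, b0)
          if (b1 < s1) nxt[[length(nxt) + 1L]] <- c(b1, s1)
        }
      }
      segs <- if (length(nxt)) do.call(rbind, nxt) else matrix(numeric(0), 0, 2)
    }
    if (nrow(segs)) out[[length(out) + 1L]] <- segs
  }
  if (length(out)) do.call(rbind, out) else matrix(numeric(0), 0, 2)
}

#' Classify one ray's hit lists into defect intervals
#'
#' Reconstructs inside/outside parity for the native and pathological solids
#' from their sorted hit lists (origin outside bone, inside the cup cavity)
#' and takes defect = inside-native AND NOT inside-pathological, clipped to
#' `[0, max_range]`. Interval endpoints and midpoints are recorded as defect
#' point stations. Rays whose hit list was truncated at the intersection cap
#' while still inside a solid cannot be resolved and are flagged invalid.
#'
#' @param native_hits,patho_hits ascending hit distances (mm, length <= 4).
#' @param max_range range cutoff (mm).
#' @param native_truncated,patho_truncated whether more in-range hits existed
#'   beyond the cap.
#' @param min_interval intervals thinner than this (mm) are treated as
#'   surface-localization noise and not recorded (0 = pure interval algebra).
#' @return list with `intervals` (k x 2 matrix), `points_t` (distances of the
#'   recorded stations), `valid`.
#' @export
classify_ray <- function(native_hits, patho_hits, max_range,
                         native_truncated = FALSE, patho_truncated = FALSE,
                         min_interval = 0) {
  # truncation at the cap loses solid parity beyond the last kept hit
  if (native_truncated || patho_truncated)
    return(list(intervals = matrix(numeric(0), 0, 2), points_t = numeric(0),
                valid = FALSE))
  N <- hit_intervals(native_hits, max_range)
  P <- hit_intervals(patho_hits, max_range)
  D <- interval_diff(N, P)
  if (nrow(D) > 0) {
    D[, 1] <- pmax(D[, 1], 0)
    D[, 2] <- pmin(D[, 2], max_range)
    D <- D[D[, 2] - D[, 1] > max(1e-9, min_interval), , drop = FALSE]
  }
  pts <- if (nrow(D) > 0)
    as.vector(t(cbind(D[, 1], (D[, 1] + D[, 2]) / 2, D[, 2]))) else numeric(0)
  list(intervals = D, points_t = pts, valid = TRUE)
}

# classify every ray of a ray_set; returns a ray_records object with defect
# points densified along each defect interval for surface reconstruction
classify_ray_set <- function(rays, native_cast, patho_cast, step = 1,
                             min_interval = 0) {
  n <- nrow(rays$directions)
  intervals <- vector("list", n)
  valid <- logical(n)
  dense_pts <- vector("list", n)
  for (i in seq_len(n)) {
    cl <- classify_ray(native_cast$hits[[i]], patho_cast$hits[[i]],
                       rays$max_range, native_cast$truncated[i],
                       patho_cast$truncated[i], min_interval = min_interval)
    intervals[[i]] <- cl$intervals
    valid[i] <- cl$valid
    if (nrow(cl$intervals) > 0) {
      ts <- unlist(lapply(seq_len(nrow(cl$intervals)), function(k) {
        t0 <- cl$intervals[k, 1]; t1 <- cl$intervals[k, 2]
        unique(c(t0, seq(t0, t1, by = step), (t0 + t1) / 2, t1))
      }))
      dense_pts[[i]] <- ts
    } else dense_pts[[i]] <- numeric(0)
  }
  structure(list(origin = rays$origin, directions = rays$directions,
                 max_range = rays$max_range,
                 native_hits = native_cast$hits, patho_hits = patho_cast$hits,
                 intervals = intervals, valid = valid,
                 point_t = dense_pts),
            class = "ray_records")
}

#' Export ray records as compressed CSV
#'
#' One row per ray: direction, up-to-four native and pathological hit
#' distances, defect-interval count and total defect length, validity flag.
#'
#' @param records a `ray_records` object.
#' @param path output path; a `.gz` suffix writes gzip-compressed text.
#' @export
write_ray_records <- function(records, path) {
  n <- nrow(records$directions)
  pad4 <- function(h) { length(h) <- 4L; h }
  nh <- t(vapply(records$native_hits, pad4, numeric(4)))
  ph <- t(vapply(records$patho_hits, pad4, numeric(4)))
  df <- data.frame(ray = seq_len(n),
                   dx = records$directions[, 1],
                   dy = records$directions[, 2],
                   dz = records$directions[, 3],
                   native_t1 = nh[, 1], native_t2 = nh[, 2],
                   native_t3 = nh[, 3], native_t4 = nh[, 4],
                   patho_t1 = ph[, 1], patho_t2 = ph[, 2],
                   patho_t3 = ph[, 3], patho_t4 = ph[, 4],
                   n_defect_intervals = vapply(records$intervals, nrow,
                                               integer(1)),
                   defect_length_mm = vapply(records$intervals,
                                             function(iv)
                                               sum(iv[, 2] - iv[, 1]),
                                             numeric(1)),
                   valid = records$valid)
  con <- if (grepl("\\.gz$", path)) gzfile(path, "w") else file(path, "w")
  on.exit(close(con))
  utils::write.csv(df, con, row.names = FALSE)
  invisible(path)
}

#' @export
print.ray_records <- function(x, ...) {
  nd <- sum(vapply(x$intervals, nrow, integer(1)) > 0)
  cat(sprintf("ray_records: %d rays (%d valid, %d with defect intervals)\n",
              nrow(x$directions), sum(x$valid), nd))
  invisible(x)
}

# world coordinates of all recorded defect points
defect_points <- function(records) {
  idx <- which(lengths(records$point_t) > 0)
  if (length(idx) == 0L) return(matrix(numeric(0), 0, 3))
  do.call(rbind, lapply(idx, function(i) {
    ts <- records$point_t[[i]]
    sweep(outer(ts, records$directions[i, ]), 2, records$origin, "+")
  }))
}

#' Cluster defect points and discard small clusters
#'
#' Single-linkage connected components at `linkage_radius`; components with
#' fewer than `min_size` points are discarded (noise rejection).
#'
#' @param points `n x 3` matrix (mm).
#' @param linkage_radius linkage distance (mm).
#' @param min_size minimum cluster size kept (200).
#' @return list of point matrices (clusters), largest first; empty list with
#'   a warning when nothing survives.
#' @export
cluster_points <- function(points, linkage_radius, min_size = 200L) {
  stopifnot(linkage_radius > 0)
  points <- as.matrix(points)
  if (nrow(points) == 0L) {
    warning("no defect points: no defect detected")
    return(list())
  }
  lab <- cpp_cluster_points(points, linkage_radius)
  sizes <- table(lab)
  keep <- names(sizes)[sizes >= min_size]
  if (length(keep) == 0L) {
    warning("all clusters below ", min_size, " points: no defect detected")
    return(list())
  }
  keep <- keep[order(-sizes[keep])]
  lapply(keep, function(k) points[lab == as.integer(k), , drop = FALSE])
}

#' Surface a defect point cloud as a watertight solid
#'
#' Voxel ball-closing reconstruction: the points are rasterized, dilated by
#' `alpha` (Euclidean distance transform), enclosed cavities are filled, and
#' the result eroded by `alpha` and surfaced. For densely sampled solids this
#' converges to the sampled shape; for large `alpha` on a convex cloud it
#' approaches the convex hull.
#'
#' @param points `n x 3` matrix (mm).
#' @param alpha closing radius (mm).
#' @param pitch reconstruction voxel pitch (mm).
#' @return a watertight [surface_mesh].
#' @export
reconstruct_surface <- function(points, alpha, pitch = 0.5) {
  points <- as.matrix(points)
  if (nrow(points) < 4L) stop("too few points to surface")
  sv <- svd(scale(points, scale = FALSE))
  if (sv$d[3] / sqrt(nrow(points)) < pitch / 4)
    stop("degenerate near-planar cluster")
  lo <- apply(points, 2, min) - alpha - 2 * pitch
  hi <- apply(points, 2, max) + alpha + 2 * pitch
  dims <- pmax(ceiling((hi - lo) / pitch), 1)
  grid <- voxel_grid(lo, dims, pitch)
  ijk <- floor(sweep(points, 2, grid$origin) / pitch) + 1L
  mask <- array(FALSE, grid$dims)
  mask[cbind(ijk[, 1], ijk[, 2], ijk[, 3])] <- TRUE
  mask <- mask_with_grid(mask, grid)
  m <- voxel_dilate(mask, alpha)
  m <- voxel_fill_cavities(m)
  m <- voxel_erode(m, alpha)
  if (!any(m)) stop("surface reconstruction produced an empty solid")
  voxel_surface(voxel_repair(m), grid)
}

#' Boolean refinement of the defect solid
#'
#' `(defect - pathological) AND native`: the subtraction sharpens the
#' defect/remaining-bone boundary, the intersection restores the articular
#' surface of the native estimate. Volume is the divergence-theorem volume of
#' the refined watertight mesh.
#'
#' @param defect surfaced defect solid.
#' @param pathological pathological pelvis mesh.
#' @param native native (defect-free) estimate mesh.
#' @param pitch Boolean voxel pitch (mm).
#' @param min_component_cm3 disconnected fragments of the refined solid
#'   smaller than this volume are discarded (solid-level noise rejection,
#'   analogous to the point-cluster floor; 0 keeps everything).
#' @param opening_radius radius (mm) of a morphological opening applied to
#'   the refined solid; sheets thinner than twice this radius - below the
#'   localization accuracy of the native estimate - are removed. 0 disables.
#' @return an object of class `defect_model` with `mesh`, `volume` (cm^3).
#' @export
refine_booleans <- function(defect, pathological, native, pitch = 0.5,
                            min_component_cm3 = 0, opening_radius = 0) {
  for (nm in c("defect", "pathological", "native")) {
    if (!mesh_is_watertight(get(nm))) stop("mesh is not watertight: ", nm)
  }
  grid <- grid_for_meshes(defect, pitch, margin = 3L)
  md <- voxelize(defect, grid = grid, check = FALSE)
  mp <- voxelize(pathological, grid = grid, check = FALSE)
  mn <- voxelize(native, grid = grid, check = FALSE)
  mask <- voxel_repair(mask_with_grid(md & !mp & mn, grid))
  if (opening_radius > 0 && any(mask)) {
    opened <- voxel_dilate(voxel_erode(mask, opening_radius), opening_radius)
    mask <- voxel_repair(mask_with_grid(mask & opened, grid))
  }
  if (min_component_cm3 > 0 && any(mask)) {
    lab <- cpp_label_components(as.logical(mask), grid$dims)
    sizes <- tabulate(lab)
    keep <- which(sizes >= min_component_cm3 * 1000 / grid$pitch^3)
    mask <- voxel_repair(mask_with_grid(
      array(lab %in% keep, grid$dims) & mask, grid))
  }
  mesh <- voxel_surface(mask, grid)
  structure(list(mesh = mesh, mask = mask,
                 volume = mesh_volume(mesh) / 1000,
                 source_points = NA_integer_, clusters_kept = NA_integer_),
            class = "defect_model")
}

#' @export
print.defect_model <- function(x, ...) {
  cat(sprintf("defect_model: %.2f cm^3 (%d clusters, %s source points)\n",
              x$volume, x$clusters_kept,
              format(x$source_points, big.mark = ",")))
  invisible(x)
}

#' Full defect reconstruction from a pathological mesh
#'
#' Pipeline composition: native estimation (two-pass shape-model fit), frame
#' derivation, spherical ray casting into both models, ray classification,
#' point clustering, surface reconstruction, Boolean refinement.
#'
#' @param pathological watertight [surface_mesh] including the defect.
#' @param model a [shape_model].
#' @param config a [run_config].
#' @return list of class `defect_reconstruction`: `defect` ([defect_model]),
#'   `records` (ray records), `frame`, `native_mesh`, `fit`.
#' @export
reconstruct_defect <- function(pathological, model, config = run_config()) {
  est <- estimate_native(model, pathological, n_modes = config$n_modes,
                         excision_factor = config$excision_factor,
                         body_axes_hint = config$body_axes_hint,
                         scale = config$similarity_scale)
  frame <- frame_from_mesh(est$native_mesh,
                           body_axes_hint = config$body_axes_hint,
                           n_points = config$rim_points)
  rays <- generate_rays(frame, config$angular_spacing,
                        max_range = config$excision_factor * frame$radius)
  ncast <- cast_ray_set(rays, est$native_mesh, config$max_intersections)
  pcast <- cast_ray_set(rays, pathological, config$max_intersections)
  min_iv <- config$min_interval
  if (is.null(min_iv)) min_iv <- 2 * config$pitch
  records <- classify_ray_set(rays, ncast, pcast, step = config$point_step,
                              min_interval = min_iv)
  pts <- defect_points(records)
  linkage <- config$linkage_radius
  if (is.null(linkage))
    linkage <- 2 * rays$max_range * config$angular_spacing * pi / 180 +
      config$point_step
  alpha <- config$alpha
  if (is.null(alpha)) alpha <- 3 * linkage
  clusters <- cluster_points(pts, linkage, config$cluster_min_size)
  if (length(clusters) == 0L) {
    empty <- structure(list(mesh = surface_mesh(matrix(numeric(0), 0, 3),
                                                matrix(integer(0), 0, 3)),
                            mask = NULL, volume = 0,
                            source_points = nrow(pts), clusters_kept = 0L),
                       class = "defect_model")
    return(structure(list(defect = empty, records = records, frame = frame,
                          native_mesh = est$native_mesh, fit = est$fit,
                          clusters = clusters),
                     class = "defect_reconstruction"))
  }
  kept_pts <- do.call(rbind, clusters)
  surf <- reconstruct_surface(kept_pts, alpha, pitch = config$pitch)
  opening <- config$opening_radius
  if (is.null(opening)) opening <- 2 * config$pitch
  dm <- refine_booleans(surf, pathological, est$native_mesh,
                        pitch = config$pitch,
                        min_component_cm3 = config$min_component_cm3,
                        opening_radius = opening)
  dm$source_points <- nrow(pts)
  dm$clusters_kept <- length(clusters)
  structure(list(defect = dm, records = records, frame = frame,
                 native_mesh = est$native_mesh, fit = est$fit,
                 clusters = clusters),
            class = "defect_reconstruction")
}

#' @export
print.defect_reconstruction <- function(x, ...) {
  cat("defect_reconstruction\n")
  print(x$frame)
  print(x$defect)
  invisible(x)
}
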