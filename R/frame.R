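#' Acetabular coordinate frame
#'
#' Hip joint centre (HJC), acetabular radius, rim plane and a right-handed
#' orthonormal triad (superior, anterior, polar). The polar axis is the rim
#' plane normal oriented out of the cup (laterally); the superior axis is the
#' projection of a global superior hint onto the rim plane; the anterior axis
#' completes the triad (`superior x anterior = polar`).
#'
#' @param hjc hip joint centre (mm).
#' @param radius acetabular radius (mm).
#' @param polar_axis unit vector out of the cup.
#' @param superior_axis unit vector in the rim plane.
#' @export
acetabular_frame <- function(hjc, radius, polar_axis, superior_axis) {
  stopifnot(radius > 0)
  p <- polar_axis / sqrt(sum(polar_axis^2))
  s <- superior_axis - sum(superior_axis * p) * p
  ns <- sqrt(sum(s^2))
  if (ns < 1e-9) stop("superior axis parallel to polar axis")
  s <- s / ns
  a <- c(p[2] * s[3] - p[3] * s[2],
         p[3] * s[1] - p[1] * s[3],
         p[1] * s[2] - p[2] * s[1])
  structure(list(hjc = as.numeric(hjc), radius = radius,
                 plane_normal = p, polar_axis = p,
                 superior_axis = s, anterior_axis = a),
            class = "acetabular_frame")
}

#' @export
print.acetabular_frame <- function(x, ...) {
  cat(sprintf("acetabular_frame: HJC (%.2f, %.2f, %.2f) mm, radius %.2f mm\n",
              x$hjc[1], x$hjc[2], x$hjc[3], x$radius))
  cat(sprintf("  polar axis (%.3f, %.3f, %.3f)\n",
              x$polar_axis[1], x$polar_axis[2], x$polar_axis[3]))
  invisible(x)
}

#' Automatically select points on the acetabular rim
#'
#' The rim is located as the closed loop of sharply concave crease edges
#' between the cup cavity and the outer surface; `n_points` stations are then
#' resampled at equal angular spacing around the loop.
#'
#' @param native a [surface_mesh] containing a concave cup.
#' @param n_points number of rim points (19).
#' @param angle_threshold minimum concave dihedral angle (degrees) for a
#'   crease edge.
#' @return `n_points x 3` matrix of rim points (mm).
#' @export
select_rim_points <- function(native, n_points = 19L, angle_threshold = 20) {
  F <- native$faces
  V <- native$vertices
  fn <- face_normals(native)$normals
  # directed edge table with owning faces
  from <- c(F[, 1], F[, 2], F[, 3])
  to <- c(F[, 2], F[, 3], F[, 1])
  face <- rep(seq_len(nrow(F)), 3)
  key <- pmin(from, to) * (nrow(V) + 1) + pmax(from, to)
  o <- order(key)
  from <- from[o]; to <- to[o]; face <- face[o]; key <- key[o]
  pair <- which(key[-1] == key[-length(key)])
  f1 <- face[pair]; f2 <- face[pair + 1L]
  a <- from[pair]; b <- to[pair]
  n1 <- fn[f1, , drop = FALSE]; n2 <- fn[f2, , drop = FALSE]
  cosang <- pmin(pmax(rowSums(n1 * n2), -1), 1)
  ang <- acos(cosang) * 180 / pi
  sharp <- ang > angle_threshold
  if (!any(sharp))
    stop("no cup detected: no sharp crease on the surface")

  # connected components of sharp-crease vertices (label propagation); the
  # rim is the component whose loop is nearly a circle (the block's own
  # corner creases form rectangular loops with high radial variation)
  ce_a <- a[sharp]; ce_b <- b[sharp]
  verts <- sort(unique(c(ce_a, ce_b)))
  ia <- match(ce_a, verts); ib <- match(ce_b, verts)
  comp <- seq_along(verts)
  repeat {
    new_comp <- comp
    for (i in seq_along(ia)) {
      mm <- min(new_comp[ia[i]], new_comp[ib[i]])
      new_comp[ia[i]] <- mm; new_comp[ib[i]] <- mm
    }
    if (identical(new_comp, comp)) break
    comp <- new_comp
  }
  best <- NULL
  best_cv <- Inf
  for (cid in unique(comp)) {
    main <- verts[comp == cid]
    if (length(main) < max(8L, n_points %/% 2L)) next
    pts <- V[main, , drop = FALSE]
    ctr0 <- colMeans(pts)
    rel0 <- sweep(pts, 2, ctr0)
    v3 <- svd(rel0)$v[, 3]
    rad0 <- sqrt(rowSums((rel0 - (rel0 %*% v3) %*% t(v3))^2))
    cv <- stats::sd(rad0) / mean(rad0)
    if (cv < best_cv) { best_cv <- cv; best <- main }
  }
  if (is.null(best) || best_cv > 0.05)
    stop("no cup detected: no circular rim crease found")
  ring <- V[best, , drop = FALSE]

  ctr <- colMeans(ring)
  sv <- svd(sweep(ring, 2, ctr))
  u1 <- sv$v[, 1]; u2 <- sv$v[, 2]
  rel <- sweep(ring, 2, ctr)
  x <- rel %*% u1; y <- rel %*% u2
  th <- atan2(y, x)
  o2 <- order(th)
  th_s <- th[o2]; ring_s <- ring[o2, , drop = FALSE]
  # close the loop for interpolation
  th_c <- c(th_s, th_s[1] + 2 * pi)
  ring_c <- rbind(ring_s, ring_s[1, ])
  targets <- th_s[1] + 2 * pi * (seq_len(n_points) - 1) / n_points
  out <- matrix(0, n_points, 3)
  for (i in seq_len(n_points)) {
    tt <- targets[i]
    j <- findInterval(tt, th_c, rightmost.closed = TRUE)
    j <- min(max(j, 1L), length(th_c) - 1L)
    span <- th_c[j + 1] - th_c[j]
    w <- if (span > 1e-12) (tt - th_c[j]) / span else 0
    out[i, ] <- (1 - w) * ring_c[j, ] + w * ring_c[j + 1, ]
  }
  out
}

#' Algebraic least-squares sphere fit
#'
#' Linear (algebraic) fit minimizing the residual of
#' `|x|^2 - 2 c.x - (r^2 - |c|^2)`; exact for points lying on a sphere.
#'
#' @param points `n x 3` matrix, `n >= 4`, not all coplanar.
#' @return list with `centre` (mm), `radius` (mm), `rms_residual` (mm).
#' @export
fit_sphere <- function(points) {
  points <- as.matrix(points)
  if (nrow(points) < 4L) stop("need at least 4 points")
  ctr <- colMeans(points)
  X <- sweep(points, 2, ctr)
  scl <- sqrt(mean(rowSums(X^2)))
  if (scl < 1e-12) stop("degenerate point set")
  X <- X / scl
  A <- cbind(2 * X, 1)
  b <- rowSums(X^2)
  sv <- svd(A)
  if (sv$d[4] < sv$d[1] * 1e-8)
    stop("degenerate sphere fit: points are coplanar")
  sol <- sv$v %*% ((1 / sv$d) * crossprod(sv$u, b))
  c0 <- sol[1:3]
  r0 <- sqrt(sol[4] + sum(c0^2))
  centre <- ctr + scl * c0
  radius <- scl * r0
  res <- sqrt(rowSums(sweep(points, 2, centre)^2)) - radius
  list(centre = as.numeric(centre), radius = radius,
       rms_residual = sqrt(mean(res^2)))
}

#' Compute the acetabular frame from rim points and a sphere fit
#'
#' The acetabular plane is the least-squares plane through the rim points;
#' the polar axis is its normal oriented away from the bone centroid; the
#' superior axis is the in-plane projection of `body_axes_hint`.
#'
#' @param rim_points `n x 3` matrix of rim points.
#' @param sphere_fit result of [fit_sphere()] on the rim points.
#' @param body_axes_hint global superior direction (default `+x`, matching
#'   the phantom convention in which the polar axis is `+z`).
#' @param bone_centroid optional centroid of the bone solid used to orient
#'   the polar axis; when `NULL` the normal with positive component along its
#'   largest-magnitude coordinate is chosen (documented fallback).
#' @return an [acetabular_frame].
#' @export
compute_frame <- function(rim_points, sphere_fit,
                          body_axes_hint = c(1, 0, 0), bone_centroid = NULL) {
  rim_points <- as.matrix(rim_points)
  ctr <- colMeans(rim_points)
  sv <- svd(sweep(rim_points, 2, ctr))
  if (sv$d[2] < sv$d[1] * 1e-8) stop("rim points are collinear")
  nrm <- sv$v[, 3]
  if (!is.null(bone_centroid)) {
    if (sum(nrm * (ctr - bone_centroid)) < 0) nrm <- -nrm
  } else if (nrm[which.max(abs(nrm))] < 0) nrm <- -nrm
  acetabular_frame(hjc = sphere_fit$centre, radius = sphere_fit$radius,
                   polar_axis = nrm, superior_axis = body_axes_hint)
}

#' Frame estimation from a native mesh
#'
#' Convenience composition: rim selection, sphere fit, frame construction
#' with the mesh centroid as the bone-side reference.
#'
#' @param native a [surface_mesh] with a cup.
#' @param body_axes_hint global superior direction.
#' @param n_points number of rim points.
#' @export
frame_from_mesh <- function(native, body_axes_hint = c(1, 0, 0),
                            n_points = 19L) {
  rim <- select_rim_points(native, n_points = n_points)
  sf <- fit_sphere(rim)
  compute_frame(rim, sf, body_axes_hint = body_axes_hint,
                bone_centroid = colMeans(native$vertices))
}

#' Excision sphere around the hip joint centre
#'
#' Icosphere of radius `factor` times the acetabular radius centred at the
#' hip joint centre, used to remove periacetabular geometry.
#'
#' @param frame an [acetabular_frame].
#' @param factor radius multiple (2.5).
#' @param subdivisions icosphere subdivision level.
#' @export
excision_sphere <- function(frame, factor = 2.5, subdivisions = 4L) {
  icosphere(radius = factor * frame$radius, centre = frame$hjc,
            subdivisions = subdivisions)
}
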