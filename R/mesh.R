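#' Triangulated surface mesh
#'
#' The universal geometry container of the package: a watertight triangulated
#' surface in millimetres. Vertices are an `n x 3` numeric matrix, faces an
#' `m x 3` integer matrix of 1-based vertex indices with outward (counter-
#' clockwise) orientation.
#'
#' @param vertices numeric matrix, one vertex per row (mm).
#' @param faces integer matrix, one triangle per row (1-based indices).
#' @return an object of class `surface_mesh`.
#' @export
surface_mesh <- function(vertices, faces) {
  vertices <- as.matrix(vertices)
  storage.mode(vertices) <- "double"
  faces <- as.matrix(faces)
  storage.mode(faces) <- "integer"
  if (ncol(vertices) != 3L) stop("vertices must have 3 columns")
  if (ncol(faces) != 3L) stop("faces must have 3 columns")
  if (nrow(faces) > 0L && (min(faces) < 1L || max(faces) > nrow(vertices)))
    stop("face indices out of range")
  structure(list(vertices = vertices, faces = faces), class = "surface_mesh")
}

#' @export
print.surface_mesh <- function(x, ...) {
  cat(sprintf("surface_mesh: %d vertices, %d faces\n",
              nrow(x$vertices), nrow(x$faces)))
  if (nrow(x$faces) > 0L) {
    wt <- mesh_is_watertight(x)
    cat(sprintf("  volume: %.2f mm^3 (%.3f cm^3), watertight: %s\n",
                mesh_volume(x), mesh_volume(x) / 1000, wt))
  }
  invisible(x)
}

#' Enclosed volume of a watertight mesh
#'
#' Signed volume by the divergence theorem; positive for outward-oriented
#' watertight surfaces.
#'
#' @param mesh a [surface_mesh].
#' @return volume in mm^3.
#' @export
mesh_volume <- function(mesh) {
  F <- mesh$faces
  if (nrow(F) == 0L) return(0)
  V <- mesh$vertices
  a <- V[F[, 1], , drop = FALSE]
  b <- V[F[, 2], , drop = FALSE]
  c_ <- V[F[, 3], , drop = FALSE]
  # sum of signed tetrahedron volumes against the origin
  det <- a[, 1] * (b[, 2] * c_[, 3] - b[, 3] * c_[, 2]) -
         a[, 2] * (b[, 1] * c_[, 3] - b[, 3] * c_[, 1]) +
         a[, 3] * (b[, 1] * c_[, 2] - b[, 2] * c_[, 1])
  sum(det) / 6
}

#' Total surface area of a mesh (mm^2)
#' @param mesh a [surface_mesh].
#' @export
mesh_area <- function(mesh) {
  F <- mesh$faces
  if (nrow(F) == 0L) return(0)
  V <- mesh$vertices
  e1 <- V[F[, 2], , drop = FALSE] - V[F[, 1], , drop = FALSE]
  e2 <- V[F[, 3], , drop = FALSE] - V[F[, 1], , drop = FALSE]
  cr <- cbind(e1[, 2] * e2[, 3] - e1[, 3] * e2[, 2],
              e1[, 3] * e2[, 1] - e1[, 1] * e2[, 3],
              e1[, 1] * e2[, 2] - e1[, 2] * e2[, 1])
  sum(sqrt(rowSums(cr^2))) / 2
}

# outward unit face normals and face areas
face_normals <- function(mesh) {
  F <- mesh$faces
  V <- mesh$vertices
  e1 <- V[F[, 2], , drop = FALSE] - V[F[, 1], , drop = FALSE]
  e2 <- V[F[, 3], , drop = FALSE] - V[F[, 1], , drop = FALSE]
  cr <- cbind(e1[, 2] * e2[, 3] - e1[, 3] * e2[, 2],
              e1[, 3] * e2[, 1] - e1[, 1] * e2[, 3],
              e1[, 1] * e2[, 2] - e1[, 2] * e2[, 1])
  nrm <- sqrt(rowSums(cr^2))
  list(normals = cr / pmax(nrm, 1e-300), areas = nrm / 2)
}

#' Watertightness check
#'
#' A mesh is watertight (closed and 2-manifold along edges) when every
#' undirected edge is used by exactly two triangles, once in each direction.
#'
#' @param mesh a [surface_mesh].
#' @return logical.
#' @export
mesh_is_watertight <- function(mesh) {
  F <- mesh$faces
  if (nrow(F) == 0L) return(FALSE)
  from <- c(F[, 1], F[, 2], F[, 3])
  to <- c(F[, 2], F[, 3], F[, 1])
  enc_dir <- from * (nrow(mesh$vertices) + 1) + to
  enc_und <- pmin(from, to) * (nrow(mesh$vertices) + 1) + pmax(from, to)
  if (anyDuplicated(enc_dir) > 0) return(FALSE)  # repeated directed edge
  s <- sort(enc_und)
  n <- length(s)
  if (n %% 2L != 0L) return(FALSE)
  odd <- seq(1L, n, by = 2L)
  # each undirected edge appears exactly twice (once per direction)
  all(s[odd] == s[odd + 1L]) &&
    (n == 2L || !any(s[odd[-1]] == s[odd[-1] - 1L]))
}

#' Number of connected components of a mesh
#' @param mesh a [surface_mesh].
#' @export
mesh_components <- function(mesh) {
  if (nrow(mesh$faces) == 0L) return(0L)
  cpp_mesh_components(nrow(mesh$vertices), mesh$faces)
}

#' Rigid / similarity transform of a mesh
#'
#' Applies `x -> scale * R x + t` to every vertex.
#'
#' @param mesh a [surface_mesh].
#' @param rotation 3x3 rotation matrix.
#' @param translation length-3 translation (mm).
#' @param scale uniform scale factor.
#' @export
mesh_transform <- function(mesh, rotation = diag(3), translation = c(0, 0, 0),
                           scale = 1) {
  v <- scale * (mesh$vertices %*% t(rotation))
  v <- sweep(v, 2, translation, "+")
  surface_mesh(v, mesh$faces)
}

#' Read an ASCII STL file
#'
#' Duplicated vertices are welded by exact coordinate string so that watertight
#' solids written by [write_stl()] round-trip with shared topology.
#'
#' @param path file path.
#' @return a [surface_mesh].
#' @export
read_stl <- function(path) {
  lines <- readLines(path, warn = FALSE)
  vl <- grep("^\\s*vertex", lines, value = TRUE)
  if (length(vl) == 0L || length(vl) %% 3L != 0L)
    stop("not a valid ASCII STL file: ", path)
  toks <- strsplit(trimws(vl), "\\s+")
  coords <- t(vapply(toks, function(tk) as.numeric(tk[2:4]), numeric(3)))
  key <- paste(coords[, 1], coords[, 2], coords[, 3])
  uk <- !duplicated(key)
  idx <- match(key, key[uk])
  surface_mesh(coords[uk, , drop = FALSE],
               matrix(idx, ncol = 3, byrow = TRUE))
}

#' Write a mesh as ASCII STL
#' @param mesh a [surface_mesh].
#' @param path file path.
#' @export
write_stl <- function(mesh, path) {
  fn <- face_normals(mesh)$normals
  V <- mesh$vertices
  F <- mesh$faces
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("solid acetrecon", con)
  if (nrow(F) > 0L) {
    tx <- sprintf(
      "facet normal %.9g %.9g %.9g\n outer loop\n  vertex %.9g %.9g %.9g\n  vertex %.9g %.9g %.9g\n  vertex %.9g %.9g %.9g\n endloop\nendfacet",
      fn[, 1], fn[, 2], fn[, 3],
      V[F[, 1], 1], V[F[, 1], 2], V[F[, 1], 3],
      V[F[, 2], 1], V[F[, 2], 2], V[F[, 2], 3],
      V[F[, 3], 1], V[F[, 3], 2], V[F[, 3], 3])
    writeLines(tx, con)
  }
  writeLines("endsolid acetrecon", con)
  invisible(path)
}

#' Icosphere mesh
#'
#' Geodesic sphere by recursive subdivision of an icosahedron; all vertices lie
#' exactly on the sphere.
#'
#' @param radius sphere radius (mm).
#' @param centre sphere centre (mm).
#' @param subdivisions number of 4-to-1 subdivision passes.
#' @export
icosphere <- function(radius = 1, centre = c(0, 0, 0), subdivisions = 4L) {
  phi <- (1 + sqrt(5)) / 2
  v <- rbind(
    c(-1, phi, 0), c(1, phi, 0), c(-1, -phi, 0), c(1, -phi, 0),
    c(0, -1, phi), c(0, 1, phi), c(0, -1, -phi), c(0, 1, -phi),
    c(phi, 0, -1), c(phi, 0, 1), c(-phi, 0, -1), c(-phi, 0, 1))
  v <- v / sqrt(rowSums(v^2))
  f <- rbind(
    c(1, 12, 6), c(1, 6, 2), c(1, 2, 8), c(1, 8, 11), c(1, 11, 12),
    c(2, 6, 10), c(6, 12, 5), c(12, 11, 3), c(11, 8, 7), c(8, 2, 9),
    c(4, 10, 5), c(4, 5, 3), c(4, 3, 7), c(4, 7, 9), c(4, 9, 10),
    c(5, 10, 6), c(3, 5, 12), c(7, 3, 11), c(9, 7, 8), c(10, 9, 2))
  for (s in seq_len(subdivisions)) {
    nv <- nrow(v)
    edge_key <- function(a, b) pmin(a, b) * (nv + 1) + pmax(a, b)
    e1 <- edge_key(f[, 1], f[, 2])
    e2 <- edge_key(f[, 2], f[, 3])
    e3 <- edge_key(f[, 3], f[, 1])
    keys <- unique(c(e1, e2, e3))
    mid_of <- function(k) {
      a <- k %/% (nv + 1); b <- k %% (nv + 1)
      m <- (v[a, , drop = FALSE] + v[b, , drop = FALSE]) / 2
      m / sqrt(rowSums(m^2))
    }
    mids <- mid_of(keys)
    v <- rbind(v, mids)
    mi <- function(k) nv + match(k, keys)
    m1 <- mi(e1); m2 <- mi(e2); m3 <- mi(e3)
    f <- rbind(cbind(f[, 1], m1, m3), cbind(f[, 2], m2, m1),
               cbind(f[, 3], m3, m2), cbind(m1, m2, m3))
  }
  surface_mesh(sweep(v * radius, 2, centre, "+"), f)
}

#' Closed cylinder mesh
#'
#' @param radius cylinder radius (mm).
#' @param base centre of the base disc (mm).
#' @param axis unit vector from base to top.
#' @param length cylinder length (mm).
#' @param n number of angular segments.
#' @export
cylinder_mesh <- function(radius, base, axis, length, n = 96L) {
  axis <- axis / sqrt(sum(axis^2))
  u <- orthonormal_basis(axis)
  ang <- 2 * pi * (seq_len(n) - 1) / n
  ring <- outer(cos(ang), u$e1 * radius) + outer(sin(ang), u$e2 * radius)
  bot <- sweep(ring, 2, base, "+")
  top <- sweep(ring, 2, base + axis * length, "+")
  v <- rbind(bot, top, base, base + axis * length)
  cb <- 2L * n + 1L; ct <- 2L * n + 2L
  nxt <- c(seq_len(n)[-1], 1L)
  side <- rbind(cbind(seq_len(n), nxt, n + nxt),
                cbind(seq_len(n), n + nxt, n + seq_len(n)))
  capb <- cbind(cb, nxt, seq_len(n))
  capt <- cbind(ct, n + seq_len(n), n + nxt)
  surface_mesh(v, rbind(side, capb, capt))
}

# two unit vectors completing a right-handed orthonormal basis with w
orthonormal_basis <- function(w) {
  w <- w / sqrt(sum(w^2))
  a <- if (abs(w[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
  e1 <- a - sum(a * w) * w
  e1 <- e1 / sqrt(sum(e1^2))
  e2 <- c(w[2] * e1[3] - w[3] * e1[2],
          w[3] * e1[1] - w[1] * e1[3],
          w[1] * e1[2] - w[2] * e1[1])
  list(e1 = e1, e2 = e2)
}

# rotation matrix about unit axis by angle (radians)
rotation_about <- function(axis, angle) {
  axis <- axis / sqrt(sum(axis^2))
  K <- matrix(c(0, -axis[3], axis[2],
                axis[3], 0, -axis[1],
                -axis[2], axis[1], 0), 3, 3, byrow = TRUE)
  diag(3) + sin(angle) * K + (1 - cos(angle)) * (K %*% K)
}

# axis-aligned bounding box of one mesh or a list of meshes (empty meshes
# contribute nothing)
mesh_bbox <- function(mesh) {
  if (inherits(mesh, "surface_mesh")) mesh <- list(mesh)
  lo <- rep(Inf, 3); hi <- rep(-Inf, 3)
  for (m in mesh) {
    if (nrow(m$vertices) == 0L) next
    lo <- pmin(lo, apply(m$vertices, 2, min))
    hi <- pmax(hi, apply(m$vertices, 2, max))
  }
  if (any(!is.finite(lo))) stop("bounding box of empty geometry")
  list(lo = lo, hi = hi)
}

# deterministic area-stratified surface samples: a barycentric lattice per
# face with subdivision matched to face area; faces are processed in groups
# of equal subdivision so uniform meshes (voxel surfaces) vectorize fully
mesh_surface_samples <- function(mesh, density) {
  V <- mesh$vertices
  F <- mesh$faces
  ar <- face_normals(mesh)$areas
  n_sub <- pmax(1L, ceiling(sqrt(2 * density * ar)))
  out <- vector("list", 0L)
  for (n in sort(unique(n_sub))) {
    rows <- which(n_sub == n)
    idx <- which(outer(0:n, 0:n, "+") <= n, arr.ind = TRUE) - 1L
    b1 <- idx[, 1] / n; b2 <- idx[, 2] / n       # k lattice stations
    a <- V[F[rows, 1], , drop = FALSE]
    e1 <- V[F[rows, 2], , drop = FALSE] - a
    e2 <- V[F[rows, 3], , drop = FALSE] - a
    # (faces x stations) per coordinate, flattened
    pts <- lapply(1:3, function(d)
      as.vector(outer(a[, d], rep(1, length(b1))) +
                  outer(e1[, d], b1) + outer(e2[, d], b2)))
    out[[length(out) + 1L]] <- cbind(pts[[1]], pts[[2]], pts[[3]])
  }
  unique(do.call(rbind, out))
}
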