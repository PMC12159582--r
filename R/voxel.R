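#' Voxel grid
#'
#' A regular axis-aligned grid of cubic voxels. `origin` is the minimum corner
#' of the grid; voxel `(i, j, k)` (1-based) has its centre at
#' `origin + (c(i, j, k) - 0.5) * pitch`.
#'
#' @param origin minimum corner (mm).
#' @param dims integer triple of voxel counts.
#' @param pitch voxel edge length (mm).
#' @export
voxel_grid <- function(origin, dims, pitch) {
  stopifnot(pitch > 0, length(origin) == 3L, length(dims) == 3L, all(dims >= 1))
  structure(list(origin = as.numeric(origin), dims = as.integer(dims),
                 pitch = as.numeric(pitch)), class = "voxel_grid")
}

#' @export
print.voxel_grid <- function(x, ...) {
  cat(sprintf("voxel_grid: %d x %d x %d at %.3g mm pitch, origin (%.2f, %.2f, %.2f)\n",
              x$dims[1], x$dims[2], x$dims[3], x$pitch,
              x$origin[1], x$origin[2], x$origin[3]))
  invisible(x)
}

#' Grid covering one or more meshes
#'
#' The grid is anchored at the bounding-box corner of the first (reference)
#' mesh, expanded by `margin` voxels on every side, and enlarged to cover all
#' further meshes so that comparisons share one grid.
#'
#' @param meshes a [surface_mesh] or list of them; the first is the reference.
#' @param pitch voxel edge length (mm).
#' @param margin margin in voxels around the joint bounding box.
#' @export
grid_for_meshes <- function(meshes, pitch, margin = 2L) {
  if (inherits(meshes, "surface_mesh")) meshes <- list(meshes)
  ref <- mesh_bbox(meshes[[1]])
  all_ <- mesh_bbox(meshes)
  origin <- ref$lo - margin * pitch
  # extend downward in whole voxels so the reference anchor is preserved
  below <- pmax(ceiling((origin - all_$lo) / pitch + margin), 0)
  origin <- origin - below * pitch
  dims <- ceiling((all_$hi - origin) / pitch) + margin
  voxel_grid(origin, dims, pitch)
}

#' Voxelize a watertight mesh
#'
#' Marks every voxel whose centre lies inside the solid, decided by crossing
#' parity along grid columns.
#'
#' @param mesh a watertight [surface_mesh].
#' @param pitch voxel edge length (mm); ignored when `grid` is given.
#' @param grid optional [voxel_grid] shared between comparisons.
#' @param check check watertightness first (error naming the mesh otherwise).
#' @param name mesh name used in error messages.
#' @return logical 3D array with attribute `grid`.
#' @export
voxelize <- function(mesh, pitch = 1, grid = NULL, check = TRUE,
                     name = deparse(substitute(mesh))) {
  if (check && !mesh_is_watertight(mesh))
    stop("mesh is not watertight: ", name)
  if (is.null(grid)) grid <- grid_for_meshes(mesh, pitch)
  mask <- cpp_voxelize(mesh$vertices, mesh$faces, grid$origin, grid$dims,
                       grid$pitch, 2L)
  attr(mask, "grid") <- grid
  mask
}

#' Volume represented by a voxel mask (mm^3)
#' @param mask logical voxel mask.
#' @param pitch voxel pitch (mm); defaults to the mask's grid.
#' @export
voxel_volume <- function(mask, pitch = NULL) {
  if (is.null(pitch)) pitch <- attr(mask, "grid")$pitch
  sum(mask) * pitch^3
}

# preserve grid attribute through logical ops
mask_with_grid <- function(mask, grid) {
  attr(mask, "grid") <- grid
  mask
}

# repair diagonal edge contacts so the boundary surface is manifold; filling
# adds at most a one-voxel band along contact lines
voxel_repair <- function(mask, grid = attr(mask, "grid")) {
  mask_with_grid(array(cpp_fix_diagonal_edges(as.logical(mask), grid$dims),
                       grid$dims), grid)
}

#' Surface a voxel mask as a watertight mesh
#'
#' Extracts the boundary faces between inside and outside voxels. The
#' divergence-theorem volume of the result equals `sum(mask) * pitch^3`
#' exactly, which keeps surfaced solids consistent with their masks.
#'
#' @param mask logical voxel mask with a `grid` attribute (or supply `grid`).
#' @param grid optional [voxel_grid].
#' @export
voxel_surface <- function(mask, grid = attr(mask, "grid")) {
  res <- cpp_voxel_surface(as.logical(mask), grid$dims, grid$origin, grid$pitch)
  surface_mesh(res$vertices, res$faces)
}

# fill background cavities not connected to the grid boundary
voxel_fill_cavities <- function(mask, grid = attr(mask, "grid")) {
  outside <- cpp_outside_background(as.logical(mask), grid$dims)
  mask_with_grid(mask | !outside, grid)
}

# morphological dilation/erosion by a Euclidean ball of radius mm
voxel_dilate <- function(mask, radius, grid = attr(mask, "grid")) {
  d2 <- cpp_edt_sq(as.logical(mask), grid$dims)
  mask_with_grid(array(d2 * grid$pitch^2 <= radius^2 + 1e-9, grid$dims), grid)
}

voxel_erode <- function(mask, radius, grid = attr(mask, "grid")) {
  d2 <- cpp_edt_sq(!as.logical(mask), grid$dims)
  # strict: a voxel exactly `radius` from the background is eroded, so a
  # sheet of thickness radius/pitch voxels does not survive
  keep <- array(d2 * grid$pitch^2 > radius^2 + 1e-9, grid$dims)
  mask_with_grid(mask & keep, grid)
}

#' Volumetric Boolean of watertight meshes
#'
#' Computes `A op B` on a shared voxel grid and surfaces the result. This is
#' the pipeline's Boolean engine; volumes quoted for Boolean results are
#' divergence-theorem volumes of the surfaced solid.
#'
#' @param op one of "difference", "intersection", "union".
#' @param A,B watertight [surface_mesh] solids.
#' @param pitch voxel pitch (mm).
#' @param grid optional shared [voxel_grid]; defaults to a grid over both.
#' @return list with `mesh` ([surface_mesh]), `mask`, and `volume` (mm^3).
#' @export
mesh_boolean <- function(op = c("difference", "intersection", "union"), A, B,
                         pitch = 0.5, grid = NULL) {
  op <- match.arg(op)
  if (is.null(grid)) grid <- grid_for_meshes(list(A, B), pitch)
  ma <- voxelize(A, grid = grid, name = "A")
  mb <- voxelize(B, grid = grid, name = "B")
  mask <- switch(op,
                 difference = ma & !mb,
                 intersection = ma & mb,
                 union = ma | mb)
  mask <- voxel_repair(mask_with_grid(mask, grid))
  mesh <- voxel_surface(mask, grid)
  list(mesh = mesh, mask = mask, volume = mesh_volume(mesh))
}
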