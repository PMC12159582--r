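#' Build a PCA statistical shape model from corresponded meshes
#'
#' Training meshes must share one template parametrization (identical vertex
#' count and face topology). Configurations are aligned by generalized
#' Procrustes analysis with similarity transforms (translation, rotation,
#' uniform scale), then principal component analysis is run on the stacked
#' vertex coordinates. Mode weights are expressed in standard deviations, so
#' a shape is `mean + sum_i w_i * sd_i * mode_i`.
#'
#' @param training list of corresponded [surface_mesh] objects (>= 2).
#' @param max_iter,tol generalized Procrustes iteration controls.
#' @return an object of class `shape_model` with elements `mean_vertices`
#'   (V x 3 mm), `modes` (3V x M, orthonormal columns), `variances` (mm^2,
#'   non-increasing), `sds`, `template_faces`, `n_training`.
#' @export
build_shape_model <- function(training, max_iter = 10L, tol = 1e-8) {
  if (length(training) < 2L) stop("need at least 2 training meshes")
  nv <- nrow(training[[1]]$vertices)
  faces <- training[[1]]$faces
  for (i in seq_along(training)) {
    m <- training[[i]]
    if (nrow(m$vertices) != nv || !identical(dim(m$faces), dim(faces)) ||
        any(m$faces != faces))
      stop("topology mismatch in training mesh ", i)
  }
  configs <- lapply(training, function(m) m$vertices)
  n <- length(configs)

  centroid_size <- function(X) sqrt(sum(scale(X, scale = FALSE)^2))
  mean_size <- mean(vapply(configs, centroid_size, numeric(1)))

  # generalized Procrustes: align all to the evolving mean with similarity fits
  ref <- configs[[1]]
  aligned <- configs
  for (it in seq_len(max_iter)) {
    aligned <- lapply(aligned, function(X) {
      tr <- similarity_transform(X, ref)
      apply_similarity(X, tr)
    })
    new_ref <- Reduce(`+`, aligned) / n
    new_ref <- new_ref * (mean_size / centroid_size(new_ref))
    if (max(abs(new_ref - ref)) < tol * mean_size) { ref <- new_ref; break }
    ref <- new_ref
  }

  X <- vapply(aligned, as.vector, numeric(3L * nv))   # 3V x n
  mu <- rowMeans(X)
  Xc <- X - mu
  sv <- svd(Xc)
  keep <- seq_len(max(1L, sum(sv$d > max(sv$d[1], 1e-300) * 1e-12)))
  if (sv$d[1] <= 0) keep <- 1L
  M <- min(length(keep), n - 1L)
  modes <- sv$u[, seq_len(M), drop = FALSE]
  variances <- (sv$d[seq_len(M)]^2) / (n - 1L)
  structure(list(mean_vertices = matrix(mu, nv, 3),
                 modes = modes,
                 variances = variances,
                 sds = sqrt(variances),
                 template_faces = faces,
                 n_training = n,
                 mean_size = mean_size),
            class = "shape_model")
}

#' @export
print.shape_model <- function(x, ...) {
  cat(sprintf("shape_model: %d vertices, %d modes from %d training shapes\n",
              nrow(x$mean_vertices), length(x$variances), x$n_training))
  tv <- sum(x$variances)
  if (tv > 0) {
    ev <- cumsum(x$variances) / tv
    cat(sprintf("  variance explained by first modes: %s\n",
                paste(sprintf("%.1f%%", 100 * utils::head(ev, 5)), collapse = ", ")))
  }
  invisible(x)
}

#' @export
summary.shape_model <- function(object, ...) {
  tv <- sum(object$variances)
  df <- data.frame(mode = seq_along(object$variances),
                   sd_mm = object$sds,
                   variance_mm2 = object$variances,
                   pct_variance = if (tv > 0) 100 * object$variances / tv else 0)
  structure(list(table = df, n_training = object$n_training,
                 n_vertices = nrow(object$mean_vertices)),
            class = "summary.shape_model")
}

#' @export
print.summary.shape_model <- function(x, ...) {
  cat(sprintf("Statistical shape model: %d training shapes, %d vertices\n",
              x$n_training, x$n_vertices))
  print(utils::head(x$table, 10), row.names = FALSE)
  invisible(x)
}

#' Generate a shape from mode weights
#'
#' @param object a [shape_model].
#' @param weights mode weights in SD units (padded with zeros).
#' @param ... unused.
#' @return a [surface_mesh] in model space.
#' @export
predict.shape_model <- function(object, weights = numeric(0), ...) {
  w <- numeric(length(object$variances))
  w[seq_along(weights)] <- weights
  v <- as.vector(object$mean_vertices) + object$modes %*% (w * object$sds)
  surface_mesh(matrix(v, ncol = 3), object$template_faces)
}

# best-fit similarity transform mapping X onto Y (row-wise correspondences):
# y ~ s * R x + t  (Umeyama); set scale = FALSE for a rigid fit
similarity_transform <- function(X, Y, scale = TRUE) {
  mx <- colMeans(X); my <- colMeans(Y)
  Xc <- sweep(X, 2, mx); Yc <- sweep(Y, 2, my)
  H <- crossprod(Xc, Yc)
  sv <- svd(H)
  d <- sign(det(sv$v %*% t(sv$u)))
  S <- diag(c(1, 1, d))
  R <- sv$v %*% S %*% t(sv$u)
  s <- if (scale) sum(diag(S) * sv$d) / sum(Xc^2) else 1
  t_ <- my - s * as.vector(R %*% mx)
  list(R = R, t = t_, s = s)
}

apply_similarity <- function(X, tr) {
  sweep(tr$s * X %*% t(tr$R), 2, tr$t, "+")
}

invert_similarity <- function(tr) {
  Rt <- t(tr$R)
  list(R = Rt, t = -as.vector(Rt %*% tr$t) / tr$s, s = 1 / tr$s)
}

#' Fit a shape model to a target mesh
#'
#' Alternates (i) similarity registration of the current fitted surface to the
#' target through closest-point correspondences and (ii) a linear least-squares
#' solve for the mode weights over unmasked vertices, until the weight change
#' drops below `tol` (SD units) or `max_iter` is reached. Weights are clamped
#' to +/- 3 SD. Masked template vertices are excluded from both steps (used to
#' ignore pathological regions).
#'
#' @param model a [shape_model].
#' @param target a [surface_mesh]; assumed roughly pre-oriented (as CT-derived
#'   anatomy is after side standardization).
#' @param n_modes number of modes used (default 20).
#' @param vertex_mask logical per template vertex; `TRUE` = exclude. At least
#'   30% of vertices must remain unmasked.
#' @param scale allow uniform scaling (similarity, default) or rigid only.
#' @param max_iter maximum alternation iterations.
#' @param tol convergence tolerance: maximum vertex displacement (mm) induced
#'   by one weight update.
#' @param rigid_warmup similarity-registration-only iterations before the
#'   alternation starts deforming the shape.
#' @param ridge ridge (mm) on the weight solve: a standard-normal prior on
#'   the SD-unit weights that suppresses noise amplification in
#'   near-zero-variance modes while leaving well-determined modes untouched.
#' @param init optional warm start: list with `w` (weights) and `tr`
#'   (similarity transform) from a previous fit; skips the rigid warm-up.
#' @return an object of class `ssm_fit`: `mode_weights` (SD units),
#'   `similarity_transform`, `fitted_mesh` (target space), `residual_rmse`
#'   (mm over unmasked vertices), `converged`, `iterations`.
#' @export
fit_shape_model <- function(model, target, n_modes = 20L, vertex_mask = NULL,
                            scale = TRUE, max_iter = 200L, tol = 1e-3,
                            rigid_warmup = 10L, ridge = 0.1, init = NULL) {
  stopifnot(inherits(model, "shape_model"), inherits(target, "surface_mesh"))
  M <- length(model$variances)
  n_modes <- min(as.integer(n_modes), M)
  nv <- nrow(model$mean_vertices)
  if (is.null(vertex_mask)) vertex_mask <- rep(FALSE, nv)
  if (length(vertex_mask) != nv) stop("vertex_mask length must match template")
  if (all(vertex_mask)) stop("vertex_mask covers the entire mesh")
  if (mean(!vertex_mask) < 0.3)
    stop("fewer than 30% of template vertices unmasked")
  un <- which(!vertex_mask)
  rows <- c(un, un + nv, un + 2L * nv)   # column-major coordinate rows
  P <- model$modes[rows, seq_len(n_modes), drop = FALSE] *
    rep(model$sds[seq_len(n_modes)], each = length(rows))
  mu_un <- as.vector(model$mean_vertices[un, , drop = FALSE])

  tv <- target$vertices
  if (!is.null(init)) {
    # warm start from a previous fit (e.g. pass 1 of the native estimation)
    w <- numeric(n_modes)
    w[seq_len(min(n_modes, length(init$w)))] <-
      init$w[seq_len(min(n_modes, length(init$w)))]
    tr <- init$tr
    rigid_warmup <- 0L
  } else {
    w <- numeric(n_modes)
    # initialization: centroid + size match, identity rotation
    X0 <- model$mean_vertices
    s0 <- sqrt(sum(scale(tv, scale = FALSE)^2) / nrow(tv)) /
      sqrt(sum(scale(X0, scale = FALSE)^2) / nrow(X0))
    if (!scale) s0 <- 1
    tr <- list(R = diag(3), t = colMeans(tv) - s0 * colMeans(X0), s = s0)
  }

  grid_handle <- cpp_mesh_grid_build(tv, target$faces)
  converged <- FALSE
  iters <- 0L
  for (it in seq_len(max_iter + rigid_warmup)) {
    iters <- it
    Xm <- matrix(mu_un + P %*% w, ncol = 3)          # model space, unmasked
    Xw <- apply_similarity(Xm, tr)
    nn <- cpp_mesh_grid_closest(grid_handle, Xw)
    Y <- nn$point                    # closest points on the target surface
    tr <- similarity_transform(Xm, Y, scale = scale)
    if (it <= rigid_warmup) next   # register first, deform later
    Yb <- apply_similarity(Y, invert_similarity(tr))  # pull back to model space
    b <- as.vector(Yb) - mu_un
    # the registration step owns the 7 similarity degrees of freedom: remove
    # from the residual anything an infinitesimal similarity transform of the
    # current shape could express, so near-degenerate modes cannot trade
    # against the transform
    J <- similarity_tangent(Xm)
    qrJ <- qr(J)
    b <- b - qr.fitted(qrJ, b)
    Pp <- P - qr.fitted(qrJ, P)
    w_new <- lssolve(Pp, b, ridge = ridge)
    w_new <- pmin(pmax(w_new, -3), 3)
    # convergence measured as the vertex displacement the update induces, so
    # noise-level jitter in near-zero-variance modes cannot stall termination
    dshape <- max(abs(P %*% (w_new - w)))
    w <- w_new
    if (dshape < tol) { converged <- TRUE; break }
  }
  full <- predict(model, w)
  fitted <- surface_mesh(apply_similarity(full$vertices, tr),
                         model$template_faces)
  res <- cpp_mesh_grid_closest(grid_handle,
                               fitted$vertices[un, , drop = FALSE])$distance
  structure(list(mode_weights = w, similarity_transform = tr,
                 fitted_mesh = fitted,
                 residual_rmse = sqrt(mean(res^2)),
                 converged = converged, iterations = iters,
                 n_modes = n_modes, vertex_mask = vertex_mask,
                 model = model),
            class = "ssm_fit")
}

# tangent basis (3n x 7) of the similarity group at configuration X:
# translations, infinitesimal rotations, uniform scale
similarity_tangent <- function(X) {
  n <- nrow(X)
  z <- numeric(n); o <- rep(1, n)
  cbind(c(o, z, z), c(z, o, z), c(z, z, o),
        c(z, -X[, 3], X[, 2]),
        c(X[, 3], z, -X[, 1]),
        c(-X[, 2], X[, 1], z),
        as.vector(X))
}

# ridge-regularized least squares via SVD. The small ridge (mm units) acts as
# a standard-normal prior on the SD-unit weights: it leaves well-determined
# modes untouched but resolves the indeterminacy between tiny-variance modes
# and the similarity transform (an infinitesimal scale/translation can mimic
# such a mode exactly), and keeps modes unsupported on a masked vertex set at
# zero instead of arbitrary values.
lssolve <- function(A, b, ridge = 0.01) {
  sv <- svd(A)
  d <- sv$d
  dinv <- d / (d^2 + ridge^2)
  as.vector(sv$v %*% (dinv * crossprod(sv$u, b)))
}

#' @export
print.ssm_fit <- function(x, ...) {
  cat(sprintf("ssm_fit: %d modes, residual RMSE %.4f mm (%s after %d iterations)\n",
              x$n_modes, x$residual_rmse,
              if (x$converged) "converged" else "not converged", x$iterations))
  cat("  weights (SD):", paste(sprintf("%.2f", utils::head(x$mode_weights, 8)),
                               collapse = " "),
      if (x$n_modes > 8) "..." else "", "\n")
  invisible(x)
}

#' @export
coef.ssm_fit <- function(object, ...) object$mode_weights

#' @export
fitted.ssm_fit <- function(object, ...) object$fitted_mesh

#' @export
residuals.ssm_fit <- function(object, target = NULL, ...) {
  if (is.null(target)) stop("supply the target mesh to compute residuals")
  un <- which(!object$vertex_mask)
  cpp_point_mesh_dist(object$fitted_mesh$vertices[un, , drop = FALSE],
                      target$vertices, target$faces)
}

#' Estimate the native, defect-free anatomy behind a pathological mesh
#'
#' Two-pass procedure: a first fit on the full pathological surface yields a
#' provisional acetabular frame; all template vertices within
#' `excision_factor` times the acetabular radius of the provisional hip joint
#' centre are then excluded and the model refitted, so pathological bone
#' around the acetabulum cannot bias the native estimate.
#'
#' @param model a [shape_model].
#' @param pathological watertight [surface_mesh] of the pathological anatomy.
#' @param n_modes number of modes (default 20).
#' @param excision_factor multiple of the acetabular radius excised (2.5).
#' @param body_axes_hint global superior direction used for frame axes.
#' @param scale allow similarity scaling in the fits.
#' @param pass1_max_iter iteration cap for the first pass: it only supplies
#'   the provisional frame and the warm start, and fitting pathological
#'   geometry exactly is neither needed nor possible.
#' @return list with `native_mesh`, `fit` (pass 2), `fit_pass1`,
#'   `provisional_frame`, `excised_fraction`.
#' @export
estimate_native <- function(model, pathological, n_modes = 20L,
                            excision_factor = 2.5,
                            body_axes_hint = c(1, 0, 0), scale = TRUE,
                            pass1_max_iter = 40L) {
  if (!mesh_is_watertight(pathological))
    stop("pathological mesh is not watertight")
  fit1 <- fit_shape_model(model, pathological, n_modes = n_modes,
                          scale = scale, max_iter = pass1_max_iter)
  frame1 <- frame_from_mesh(fit1$fitted_mesh, body_axes_hint = body_axes_hint)
  d <- sqrt(rowSums(sweep(fit1$fitted_mesh$vertices, 2, frame1$hjc)^2))
  mask <- d < excision_factor * frame1$radius
  if (mean(mask) > 0.7)
    stop(sprintf("excision would remove %.0f%% of the surface (> 70%%)",
                 100 * mean(mask)))
  # pass 2 is a local optimization over a reduced (wall-only) surface and can
  # inherit a bad pose either way: warm-started from pass 1 (which may have
  # sunk into a massive defect) or cold (which may wander without the cup).
  # Run both and keep the better fit of the retained surface.
  fit2_warm <- fit_shape_model(model, pathological, n_modes = n_modes,
                               vertex_mask = mask, scale = scale,
                               init = list(w = fit1$mode_weights,
                                           tr = fit1$similarity_transform))
  fit2_cold <- fit_shape_model(model, pathological, n_modes = n_modes,
                               vertex_mask = mask, scale = scale)
  fit2 <- if (fit2_warm$residual_rmse <= fit2_cold$residual_rmse) fit2_warm
          else fit2_cold
  list(native_mesh = fit2$fitted_mesh, fit = fit2, fit_pass1 = fit1,
       provisional_frame = frame1, excised_fraction = mean(mask))
}
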