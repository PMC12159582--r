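test_that("model build enforces topology and produces orthonormal modes", {
  model <- test_model()
  M <- model$modes
  expect_lt(max(abs(crossprod(M) - diag(ncol(M)))), 1e-10)
  expect_true(all(diff(model$variances) <= 1e-9))
  expect_lte(length(model$variances), model$n_training - 1L)

  pop <- test_population()
  bad <- pop
  bad[[3]] <- icosphere(10, c(0, 0, 0), 2)
  expect_error(build_shape_model(bad), "mesh 3")
})

test_that("identical training shapes give zero variance", {
  m <- test_phantom()$native_mesh
  model <- build_shape_model(rep(list(m), 10))
  expect_lt(max(model$variances) / max(sum(m$vertices^2), 1), 1e-9)
})

test_that("training members are reconstructed exactly with all modes", {
  pop <- test_population()
  model <- build_shape_model(pop)
  # project an aligned member onto the full mode basis: completeness
  target <- pop[[5]]
  tr <- acetrecon:::similarity_transform(target$vertices, model$mean_vertices)
  al <- acetrecon:::apply_similarity(target$vertices, tr)
  b <- as.vector(al) - as.vector(model$mean_vertices)
  w <- crossprod(model$modes, b)
  rec <- as.vector(model$mean_vertices) + model$modes %*% w
  err <- matrix(rec, ncol = 3) - al
  expect_lt(sqrt(mean(rowSums(err^2))), 1e-6)
})

test_that("a single-parameter family concentrates variance in mode 1", {
  tpl <- acetrecon:::phantom_template(phantom_params())
  radii <- seq(21, 29, length.out = 12)
  pop <- lapply(radii, function(r)
    make_phantom(phantom_params(cup_radius = r, template = tpl),
                 seed = 1)$native_mesh)
  model <- build_shape_model(pop)
  expect_gt(model$variances[1] / sum(model$variances), 0.95)
})

test_that("mode weights are recovered from generated targets", {
  model <- test_model()
  w_true <- c(1.5, -0.8, 0.6, rep(0, 17))
  target <- predict(model, w_true)

  f0 <- fit_shape_model(model, predict(model))
  expect_lt(max(abs(coef(f0))), 1e-6)
  expect_lt(f0$residual_rmse, 1e-8)

  f <- fit_shape_model(model, target)
  expect_lt(max(abs(coef(f) - w_true)), 0.05)
  expect_true(f$converged)

  # 20% of vertices masked in the cup region
  d <- sqrt(rowSums(predict(model)$vertices^2))
  mask <- rank(d, ties.method = "first") <= 0.2 * length(d)
  fm <- fit_shape_model(model, target, vertex_mask = mask)
  expect_lt(max(abs(coef(fm) - w_true)), 0.15)

  expect_error(fit_shape_model(model, target,
                               vertex_mask = rep(TRUE, length(d))),
               "entire mesh")
  expect_error(fit_shape_model(model, target,
                               vertex_mask = rank(d) > 0.1 * length(d)),
               "30%")
})

test_that("fitting is equivariant under rigid motion of the target", {
  model <- test_model()
  w_true <- c(1.5, -0.8, 0.6, rep(0, 17))
  target <- predict(model, w_true)
  R <- acetrecon:::rotation_about(c(1, 2, 3), 10 * pi / 180)
  moved <- mesh_transform(target, R, c(10, -5, 8))
  f <- fit_shape_model(model, moved)
  expect_lt(max(abs(coef(f) - w_true)), 0.05)
})

test_that("reconstruction error is non-increasing in the number of modes", {
  model <- test_model()
  set.seed(31)
  for (k in 1:5) {
    w <- rnorm(6, 0, 1)
    target <- predict(model, w)
    errs <- vapply(c(2L, 4L, 6L, 10L), function(nm)
      fit_shape_model(model, target, n_modes = nm)$residual_rmse, numeric(1))
    # non-increasing up to the fit's own convergence tolerance (1e-3 mm)
    expect_true(all(diff(errs) <= 1e-3))
  }
})

test_that("native estimation recovers a defect-free member", {
  model <- test_model()
  pop <- test_population()
  member <- pop[[7]]
  est <- estimate_native(model, member)
  d <- acetrecon:::cpp_point_mesh_dist(est$native_mesh$vertices,
                                       member$vertices, member$faces)
  expect_lt(sqrt(mean(d^2)), 0.5)
  expect_lt(est$excised_fraction, 0.7)
})

test_that("pass-2 residual over retained bone does not exceed pass 1", {
  model <- test_model()
  tpl <- acetrecon:::phantom_template(phantom_params())
  worse <- 0L
  for (s in 1:3) {
    prm <- acetrecon:::with_seed(100 + s,
                                 draw_phantom_params(template = tpl))
    case <- make_phantom(prm, seed = 100 + s)
    spec <- defect_presets("medium", case$truth_frame, seed = s)
    case <- carve_defect(case, spec, pitch = 0.5)
    est <- estimate_native(model, case$pathological_mesh)
    un <- which(!est$fit$vertex_mask)
    r1 <- acetrecon:::cpp_point_mesh_dist(
      est$fit_pass1$fitted_mesh$vertices[un, , drop = FALSE],
      case$pathological_mesh$vertices, case$pathological_mesh$faces)
    r2 <- acetrecon:::cpp_point_mesh_dist(
      est$fit$fitted_mesh$vertices[un, , drop = FALSE],
      case$pathological_mesh$vertices, case$pathological_mesh$faces)
    if (sqrt(mean(r2^2)) > sqrt(mean(r1^2)) + 1e-9) worse <- worse + 1L
  }
  expect_equal(worse, 0L)
})
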