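#' Pipeline configuration
#'
#' All tunable constants of the reconstruction pipeline in one place. The
#' defaults are the method's published operating point: 2.5x acetabular
#' radius excision and ray range, 20 shape-model modes, 19 rim points, at
#' most 4 ray intersections, 200-point cluster floor, region extents
#' 2.2r / 1.9r / 1.9r and 0.86r medial-wall cylinder radius.
#'
#' @param angular_spacing ray angular spacing (degrees).
#' @param n_modes shape-model modes used in fitting.
#' @param cluster_min_size minimum defect-point cluster size kept.
#' @param excision_factor excision-sphere and ray-range radius multiple.
#' @param region_factors named radial extents of the four regions (x radius).
#' @param medial_length_factor medial-wall cylinder length (x radius).
#' @param pitch working voxel pitch for carving/Booleans (mm).
#' @param dice_pitch voxel pitch for mask comparisons (mm).
#' @param max_intersections per-ray intersection cap.
#' @param rim_points number of automatically selected rim points.
#' @param min_component_cm3 minimum volume (cm^3) of disconnected fragments
#'   kept after Boolean refinement.
#' @param opening_radius morphological opening radius (mm) applied to the
#'   refined defect solid; `NULL` = twice the voxel pitch (sheets thinner
#'   than the native-estimate localization accuracy are removed).
#' @param min_interval minimum defect-interval thickness recorded (mm);
#'   `NULL` = twice the voxel pitch (thinner gaps are below the resolution of
#'   the surfaced models and indistinguishable from surface noise).
#' @param linkage_radius cluster linkage distance (mm); `NULL` = auto
#'   (twice the arc length subtended by one ray spacing at maximum range,
#'   plus the point step).
#' @param alpha surfacing closing radius (mm); `NULL` = 3x linkage radius.
#' @param point_step densification step along defect intervals (mm).
#' @param body_axes_hint global superior direction.
#' @param similarity_scale allow uniform scale in shape-model fits.
#' @param n_training training-population size for the default shape model.
#' @param sample_density Hausdorff surface-sampling density (per mm^2).
#' @param seed base seed for synthetic data generation.
#' @return an object of class `run_config` with a reproducible `hash`.
#' @export
run_config <- function(angular_spacing = 1,
                       n_modes = 20L,
                       cluster_min_size = 200L,
                       excision_factor = 2.5,
                       region_factors = c(superior = 2.2, anterior = 1.9,
                                          posterior = 1.9, medial_wall = 0.86),
                       medial_length_factor = 2.5,
                       pitch = 0.5,
                       dice_pitch = 1.0,
                       max_intersections = 4L,
                       rim_points = 19L,
                       min_interval = NULL,
                       min_component_cm3 = 0.5,
                       opening_radius = NULL,
                       linkage_radius = NULL,
                       alpha = NULL,
                       point_step = 1,
                       body_axes_hint = c(1, 0, 0),
                       similarity_scale = TRUE,
                       n_training = 57L,
                       sample_density = 10,
                       seed = 1L) {
  stopifnot(excision_factor > 0, all(region_factors > 0), pitch > 0,
            dice_pitch > 0, n_modes >= 1, cluster_min_size >= 0,
            max_intersections >= 1, rim_points >= 4)
  cfg <- list(angular_spacing = angular_spacing, n_modes = as.integer(n_modes),
              cluster_min_size = as.integer(cluster_min_size),
              excision_factor = excision_factor,
              region_factors = region_factors,
              medial_length_factor = medial_length_factor,
              pitch = pitch, dice_pitch = dice_pitch,
              max_intersections = as.integer(max_intersections),
              rim_points = as.integer(rim_points),
              min_interval = min_interval,
              min_component_cm3 = min_component_cm3,
              opening_radius = opening_radius,
              linkage_radius = linkage_radius, alpha = alpha,
              point_step = point_step, body_axes_hint = body_axes_hint,
              similarity_scale = similarity_scale,
              n_training = as.integer(n_training),
              sample_density = sample_density, seed = as.integer(seed))
  cfg$hash <- config_hash(cfg)
  structure(cfg, class = "run_config")
}

config_hash <- function(cfg) {
  cfg$hash <- NULL
  f <- tempfile()
  on.exit(unlink(f))
  dput(cfg, file = f)
  unname(tools::md5sum(f))
}

#' @export
print.run_config <- function(x, ...) {
  cat("run_config", substr(x$hash, 1, 8), "\n")
  cat(sprintf("  rays: %.2f deg spacing, <= %d intersections, range %.1fx radius\n",
              x$angular_spacing, x$max_intersections, x$excision_factor))
  cat(sprintf("  shape model: %d modes from %d training shapes; %d rim points\n",
              x$n_modes, x$n_training, x$rim_points))
  cat(sprintf("  clustering floor %d points; voxel pitch %.2f mm (dice %.2f mm)\n",
              x$cluster_min_size, x$pitch, x$dice_pitch))
  cat(sprintf("  regions: %.2f / %.2f / %.2f / %.2fr\n",
              x$region_factors[["superior"]], x$region_factors[["anterior"]],
              x$region_factors[["posterior"]], x$region_factors[["medial_wall"]]))
  invisible(x)
}

#' Defect presets for the synthetic suite
#'
#' Three size classes of carved defects (nominal truth volumes around 10, 30
#' and 80 cm^3, spanning the clinical range from contained cavitary defects
#' to massive multi-regional bone loss), positioned relative to the true
#' acetabular frame. `seed` jitters primitive centres and sizes.
#'
#' @param size "small", "medium" (two-lobed) or "large".
#' @param frame the phantom's true [acetabular_frame].
#' @param seed integer jitter seed.
#' @return a [defect_spec].
#' @export
defect_presets <- function(size = c("small", "medium", "large"), frame,
                           seed = 1L) {
  size <- match.arg(size)
  r <- frame$radius
  c0 <- frame$hjc
  S <- frame$superior_axis; A <- frame$anterior_axis; P <- frame$polar_axis
  with_seed(seed, {
    jc <- function() stats::rnorm(3, 0, 0.04 * r)
    jr <- function() 1 + stats::rnorm(1, 0, 0.03)
    prims <- switch(size,
      small = list(   # contained cavitary loss at the superior dome
        defect_primitive("sphere", c0 + 0.45 * r * S - 0.85 * r * P + jc(),
                         0.65 * r * jr())),
      medium = list(  # two-lobed superior + posterior column loss
        defect_primitive("sphere", c0 + 0.6 * r * S - 0.8 * r * P + jc(),
                         0.78 * r * jr()),
        defect_primitive("sphere", c0 - 0.6 * r * A - 0.8 * r * P + jc(),
                         0.72 * r * jr())),
      large = list(   # massive central + posterosuperior destruction
        defect_primitive("ellipsoid", c0 - 0.8 * r * P + jc(),
                         c(1.45, 1.2, 1.0) * r * jr(),
                         orientation = cbind(S, A, P)),
        defect_primitive("sphere", c0 - 0.6 * r * A + 0.4 * r * S -
                           0.7 * r * P + jc(), 0.8 * r * jr())))
    defect_spec(prims)
  })
}

#' Generate the standard synthetic validation suite
#'
#' `length(sizes) * seeds_per_size` carved cases whose phantom parameters are
#' drawn from the training population model (sharing its template) and whose
#' defects come from [defect_presets()], with voxel-oracle ground truth.
#'
#' @param config a [run_config].
#' @param sizes defect size classes.
#' @param seeds_per_size cases per class.
#' @param param_distribution population model for case anatomy.
#' @return list of [synthetic_case] objects with `size_class` set.
#' @export
synthetic_suite <- function(config = run_config(),
                            sizes = c("small", "medium", "large"),
                            seeds_per_size = 4L,
                            param_distribution = population_model()) {
  tpl <- phantom_template(phantom_params(
    block_half_extents = param_distribution$block_half_extents,
    cup_radius = param_distribution$cup_radius,
    surface_resolution = param_distribution$surface_resolution,
    rim_saddle = param_distribution$rim_saddle))
  cases <- list()
  for (si in seq_along(sizes)) {
    for (k in seq_len(seeds_per_size)) {
      cseed <- config$seed + 1000L * si + k
      prm <- with_seed(cseed,
                       draw_phantom_params(param_distribution, template = tpl))
      case <- make_phantom(prm, seed = cseed)
      spec <- defect_presets(sizes[si], case$truth_frame, seed = cseed)
      case <- carve_defect(case, spec, pitch = config$pitch)
      case$size_class <- sizes[si]
      case$case_id <- sprintf("%s_%02d", sizes[si], k)
      cases[[length(cases) + 1L]] <- case
    }
  }
  cases
}

#' Run the full pipeline over a set of synthetic cases
#'
#' Builds (or reuses) the shape model, reconstructs every case's defect,
#' computes regional metrics and validates against the voxel-oracle ground
#' truth. Failures are captured per case and the batch continues.
#'
#' @param config a [run_config].
#' @param model optional prebuilt [shape_model].
#' @param cases optional list of [synthetic_case]; defaults to the standard
#'   12-case suite.
#' @param verbose print per-case progress.
#' @return list of per-case reports (class `pipeline_reports`).
#' @export
run_pipeline <- function(config = run_config(), model = NULL, cases = NULL,
                         verbose = TRUE) {
  if (is.null(model)) {
    training <- sample_population(config$n_training, seed = config$seed)
    model <- build_shape_model(training)
  }
  if (is.null(cases)) cases <- synthetic_suite(config)
  reports <- vector("list", length(cases))
  on.exit(gc(verbose = FALSE), add = TRUE)
  for (i in seq_along(cases)) {
    gc(verbose = FALSE)
    case <- cases[[i]]
    id <- case$case_id %||% sprintf("case_%02d", i)
    t0 <- proc.time()[["elapsed"]]
    reports[[i]] <- tryCatch({
      rec <- reconstruct_defect(case$pathological_mesh, model, config)
      metrics <- regional_metrics(rec$defect, rec$native_mesh, rec$frame,
                                  rec$records, pitch = config$pitch,
                                  factors = config$region_factors,
                                  medial_length_factor = config$medial_length_factor)
      validation <- NULL
      truth_volume <- case$truth_defect_volume / 1000
      if (!is.null(case$truth_defect_indices)) {
        truth_mesh <- voxel_surface(truth_mask(case), case$truth_grid)
        validation <- validate_defect(rec$defect, truth_mesh,
                                      pitch = config$dice_pitch,
                                      sample_density = config$sample_density)
      }
      el <- proc.time()[["elapsed"]] - t0
      if (verbose)
        message(sprintf("[%s] defect %.2f cm^3 (truth %.2f), dice %s, %.1f s",
                        id, rec$defect$volume, truth_volume,
                        if (is.null(validation)) "-" else
                          sprintf("%.3f", validation$dice), el))
      structure(list(case_id = id, size_class = case$size_class,
                     seed = case$seed, frame = rec$frame,
                     defect_volume = rec$defect$volume,
                     truth_volume = truth_volume,
                     metrics = metrics, validation = validation,
                     truth_regional = case$truth_regional,
                     elapsed_s = el, config_hash = config$hash,
                     error = NULL),
                class = "case_report")
    }, error = function(e) {
      structure(list(case_id = id, size_class = case$size_class,
                     seed = case$seed, error = conditionMessage(e),
                     elapsed_s = proc.time()[["elapsed"]] - t0,
                     config_hash = config$hash),
                class = "case_report")
    })
  }
  structure(reports, class = "pipeline_reports", config = config)
}

#' @export
print.case_report <- function(x, ...) {
  if (!is.null(x$error)) {
    cat(sprintf("case_report %s: FAILED (%s)\n", x$case_id, x$error))
    return(invisible(x))
  }
  cat(sprintf("case_report %s (%s): defect %.2f cm^3, truth %.2f cm^3\n",
              x$case_id, x$size_class %||% "?", x$defect_volume,
              x$truth_volume))
  if (!is.null(x$validation)) print(x$validation)
  invisible(x)
}

#' @export
print.pipeline_reports <- function(x, ...) {
  ok <- vapply(x, function(r) is.null(r$error), logical(1))
  cat(sprintf("pipeline_reports: %d cases (%d ok, %d failed)\n",
              length(x), sum(ok), sum(!ok)))
  invisible(x)
}

#' Summarize a batch of case reports by defect size class
#'
#' Mean and standard deviation of total and regional ADV (cm^3), RDV (%) and
#' DD (mm) per size class, one row per class (regions as column groups).
#'
#' @param reports a `pipeline_reports` list (or list of `case_report`).
#' @return data.frame summary.
#' @export
batch_summary <- function(reports) {
  rows <- lapply(reports, function(r) {
    if (!is.null(r$error)) return(NULL)
    m <- r$metrics
    vals <- list(size_class = r$size_class %||% "all")
    for (rg in m$region) {
      mi <- m[m$region == rg, ]
      vals[[paste0(rg, "_adv_cm3")]] <- mi$adv_cm3
      vals[[paste0(rg, "_rdv_pct")]] <- mi$rdv_pct
      vals[[paste0(rg, "_dd_mm")]] <- mi$dd_mm
    }
    as.data.frame(vals)
  })
  rows <- do.call(rbind, rows[!vapply(rows, is.null, logical(1))])
  if (is.null(rows) || nrow(rows) == 0L) stop("no successful reports")
  classes <- unique(rows$size_class)
  num <- setdiff(names(rows), "size_class")
  out <- do.call(rbind, lapply(classes, function(cl) {
    sub <- rows[rows$size_class == cl, num, drop = FALSE]
    mean_ <- vapply(sub, mean, numeric(1))
    sd_ <- vapply(sub, function(v) if (length(v) > 1) stats::sd(v) else 0,
                  numeric(1))
    df <- data.frame(size_class = cl, n = nrow(sub))
    for (nm in num) {
      df[[paste0(nm, "_mean")]] <- mean_[[nm]]
      df[[paste0(nm, "_sd")]] <- sd_[[nm]]
    }
    df
  }))
  rownames(out) <- NULL
  out
}
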