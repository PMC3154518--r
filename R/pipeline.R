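.vertascan_cache <- new.env(parent = emptyenv())

#' Default spine-curvature model
#'
#' A curvature model trained on synthetic spine geometries (no clinical
#' training set ships with the package). Deterministic; cached per session.
#'
#' @return A \code{curvature_model} with 10 landmarks.
#' @export
default_curvature_model <- function() {
  if (is.null(.vertascan_cache$curvature)) {
    .vertascan_cache$curvature <-
      build_curvature_model(synthetic_curvature_samples(50, seed = 42))
  }
  .vertascan_cache$curvature
}

#' Default vertebra shape model
#'
#' A 12-landmark per-vertebra shape model trained on synthetic jittered
#' quadrilateral vertebra shapes. Deterministic; cached per session.
#'
#' @return A \code{shape_model}.
#' @export
default_vertebra_model <- function() {
  if (is.null(.vertascan_cache$vertebra)) {
    shapes <- synthetic_vertebra_shapes(100, seed = 43)
    al <- procrustes_align_set(shapes)
    .vertascan_cache$vertebra <- build_pca_model(al$aligned)
  }
  .vertascan_cache$vertebra
}

#' Default grey-level profile model
#'
#' Profile models trained on synthetic radiographs rendered at the default
#' study conditions, using their ground-truth shapes. Deterministic;
#' cached per session.
#'
#' @param k Profile half-length.
#' @return A \code{profile_model}.
#' @export
default_profile_model <- function(k = 6) {
  key <- paste0("profiles_k", k)
  if (is.null(.vertascan_cache[[key]])) {
    imgs <- list(); shapes <- list()
    for (s in 101:106) {
      r <- render_radiograph(synthetic_spec(seed = s))
      for (v in names(r$truth$shapes)) {
        imgs[[length(imgs) + 1]] <- r$image
        shapes[[length(shapes) + 1]] <- r$truth$shapes[[v]]
      }
    }
    .vertascan_cache[[key]] <- build_profile_models(imgs, shapes, k = k)
  }
  .vertascan_cache[[key]]
}

#' Pipeline configuration
#'
#' Bundles the per-stage parameters of the end-to-end chain (enhance,
#' edges, corners, locate, segment). Models left \code{NULL} fall back to
#' the package's synthetic-trained defaults.
#'
#' @param clahe A \code{\link{clahe_params}} object.
#' @param canny A \code{\link{canny_params}} object; the default uses
#'   absolute hysteresis thresholds suited to the 0-255 enhanced images.
#' @param epsilon Douglas-Peucker threshold (pixels).
#' @param min_contour_length Minimum traced-contour length (pixels).
#' @param min_angle,max_angle Corner turning-angle band (degrees).
#' @param curvature_model,shape_model,profile_model Optional trained
#'   models.
#' @param profile_k Profile half-length.
#' @param search_range ASM candidate half-range per step.
#' @param tol ASM convergence threshold (pixels).
#' @param max_iter ASM iteration cap.
#' @param anchor_indices Anterior-corner landmark indices in the vertebra
#'   shape.
#' @param max_level Image bit-depth top (255 for 8-bit).
#' @return An object of class \code{pipeline_config}.
#' @export
pipeline_config <- function(clahe = clahe_params(),
                            canny = canny_params(sigma = 1.4, low = 20,
                                                 high = 40,
                                                 threshold_mode = "absolute"),
                            epsilon = 4, min_contour_length = 20,
                            min_angle = 30, max_angle = 150,
                            curvature_model = NULL, shape_model = NULL,
                            profile_model = NULL, profile_k = 6,
                            search_range = 4, tol = 0.5, max_iter = 50,
                            anchor_indices = c(1, 10), max_level = 255) {
  structure(as.list(environment()), class = "pipeline_config")
}

#' Run the full detection and segmentation pipeline
#'
#' Executes the chain in order: contrast-limited adaptive histogram
#' equalization, Canny edge detection, contour tracing with
#' Douglas-Peucker corner detection, curvature-model vertebra
#' localization anchored on the two ROI clicks, and per-vertebra Active
#' Shape Model segmentation. Enhancement and edge detection serve the
#' corner-based initialization; the ASM profiles are matched on the
#' original image.
#'
#' @param img Intensity matrix or image file path.
#' @param clicks A \code{\link{roi_clicks}} object (upper anterior C3,
#'   lower anterior C7).
#' @param config A \code{\link{pipeline_config}}.
#' @return An object of class \code{vertascan_result}: the enhanced image,
#'   edge mask, contours, corners, anchors, per-vertebra initial shapes
#'   and \code{asm_fit} results, and \code{shapes} (final per-vertebra
#'   landmark matrices).
#' @export
run_pipeline <- function(img, clicks, config = pipeline_config()) {
  stopifnot(inherits(clicks, "roi_clicks"), inherits(config, "pipeline_config"))
  if (is.character(img)) img <- read_gray(img, max_level = config$max_level)
  cm <- config$curvature_model %||% default_curvature_model()
  sm <- config$shape_model %||% default_vertebra_model()
  pm <- config$profile_model %||% default_profile_model(config$profile_k)

  enhanced <- clahe(img, config$clahe, max_level = config$max_level)
  edges <- canny(enhanced, config$canny)
  contours <- trace_contours(edges, config$min_contour_length)
  corners <- detect_corners(contours, config$epsilon, config$min_angle,
                            config$max_angle)
  if (nrow(corners) == 0) stop("no corners detected; check edge parameters")
  positioned <- align_model_to_roi(cm, clicks)
  anchors <- match_corners(positioned, corners, clicks)
  inits <- init_vertebra_shapes(anchors, sm, config$anchor_indices)
  fits <- lapply(inits, function(s) {
    segment_vertebra(img, s, sm, pm, tol = config$tol,
                     max_iter = config$max_iter,
                     search_range = config$search_range)
  })
  structure(list(enhanced = enhanced, edges = edges, contours = contours,
                 corners = corners, positioned = positioned,
                 anchors = anchors, inits = inits, fits = fits,
                 shapes = lapply(fits, `[[`, "final_shape"),
                 config = config),
            class = "vertascan_result")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Batch processing with aggregate statistics
#'
#' Runs \code{\link{run_pipeline}} over a set of images, isolating
#' per-image failures, and aggregates a per-vertebra error report when
#' gold-standard shapes are supplied.
#'
#' @param imgs List of intensity matrices or paths.
#' @param clicks List of \code{\link{roi_clicks}}, one per image.
#' @param config A \code{\link{pipeline_config}}.
#' @param gold Optional list (one element per image) of named per-vertebra
#'   gold shapes.
#' @return A list with \code{results} (per image; \code{NULL} where the
#'   run failed), \code{errors} (messages for failed images) and
#'   \code{report} (an \code{\link{error_report}} data frame, or
#'   \code{NULL} without gold standards).
#' @export
batch_process <- function(imgs, clicks, config = pipeline_config(),
                          gold = NULL) {
  stopifnot(length(imgs) >= 1, length(clicks) == length(imgs))
  results <- vector("list", length(imgs))
  errors <- rep(NA_character_, length(imgs))
  for (i in seq_along(imgs)) {
    results[[i]] <- tryCatch(run_pipeline(imgs[[i]], clicks[[i]], config),
                             error = function(e) {
                               errors[i] <<- conditionMessage(e)
                               NULL
                             })
  }
  report <- NULL
  if (!is.null(gold)) {
    ok <- !vapply(results, is.null, TRUE)
    if (sum(ok) >= 2) {
      report <- error_report(gold[ok],
                             lapply(results[ok], `[[`, "shapes"))
    }
  }
  list(results = results, errors = errors, report = report)
}
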