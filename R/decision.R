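## Frame-adequacy gating, the capture loop, and the three-way clinical
## decision. A frame is usable only when every required landmark is present
## and its geometric fits are trustworthy; a cine sweep with too few
## adequate frames is inconclusive (repeat scan), otherwise the median
## alpha angle and coverage over adequate frames are compared against Graf
## normality thresholds.

DECISION_LABELS <- c("HEALTHY", "FOLLOW_UP", "INCONCLUSIVE")

#' Frame-adequacy thresholds
#'
#' @param required_classes landmark classes that must be present (1 =
#'   acetabulum-ilium complex, 2 = femoral head).
#' @param min_class_area_px minimum pixel area per required class.
#' @param max_line_residual_px maximum RMS residual of the baseline/roof
#'   line fits.
#' @param max_circle_residual_px maximum RMS radial residual of the head
#'   circle fit.
#' @param min_head_radius_px minimum fitted head radius.
#' @return list of class `adequacy_thresholds`.
#' @export
adequacy_thresholds <- function(required_classes = c(1L, 2L),
                                min_class_area_px = 40,
                                max_line_residual_px = 2.5,
                                max_circle_residual_px = 2.0,
                                min_head_radius_px = 8) {
  check_scalar(min_class_area_px, "min_class_area_px", min = 1)
  check_scalar(max_line_residual_px, "max_line_residual_px", min = 1e-9)
  check_scalar(max_circle_residual_px, "max_circle_residual_px", min = 1e-9)
  check_scalar(min_head_radius_px, "min_head_radius_px", min = 1e-9)
  structure(list(required_classes = as.integer(required_classes),
                 min_class_area_px = min_class_area_px,
                 max_line_residual_px = max_line_residual_px,
                 max_circle_residual_px = max_circle_residual_px,
                 min_head_radius_px = min_head_radius_px),
            class = "adequacy_thresholds")
}

#' Decision thresholds
#'
#' The Graf-methodology normality cutoffs: a hip is healthy when the
#' aggregated alpha angle is at least `alpha_healthy_deg` and the
#' aggregated femoral head coverage at least `fhc_healthy` (boundary
#' equality counts as healthy). Sweeps with fewer than
#' `min_adequate_frames` usable frames are inconclusive.
#'
#' @param alpha_healthy_deg alpha normality cutoff (degrees).
#' @param fhc_healthy coverage normality cutoff (fraction).
#' @param min_adequate_frames adequate frames needed for a conclusive scan.
#' @param aggregator per-sweep statistic over adequate frames; only
#'   `"median"` (robust to residual outlier frames).
#' @return list of class `decision_thresholds`.
#' @export
decision_thresholds <- function(alpha_healthy_deg = 60.0, fhc_healthy = 0.50,
                                min_adequate_frames = 5L,
                                aggregator = "median") {
  check_scalar(alpha_healthy_deg, "alpha_healthy_deg")
  check_scalar(fhc_healthy, "fhc_healthy")
  check_scalar(min_adequate_frames, "min_adequate_frames", min = 1, integer = TRUE)
  if (!identical(aggregator, "median"))
    hs_validation_error("only the 'median' aggregator is supported")
  structure(list(alpha_healthy_deg = alpha_healthy_deg,
                 fhc_healthy = fhc_healthy,
                 min_adequate_frames = as.integer(min_adequate_frames),
                 aggregator = aggregator),
            class = "decision_thresholds")
}

#' Assess one frame's landmark adequacy
#'
#' A frame is adequate when every required landmark class is present with
#' sufficient area, the line fits are within the residual bound, the head
#' circle fit is within its residual bound and the fitted head radius is
#' large enough. Failures are enumerated as reason codes
#' (`MISSING_CLASS_1`, `MISSING_CLASS_2`, `SMALL_CLASS_1`, `SMALL_CLASS_2`,
#' `HIGH_LINE_RESIDUAL`, `HIGH_CIRCLE_RESIDUAL`, `SMALL_HEAD`,
#' `FIT_FAILED`), never raised as errors.
#'
#' @param mask integer label matrix.
#' @param adequacy an [adequacy_thresholds()].
#' @param frame_id identifier recorded in the assessment.
#' @param config a [geometry_config()] for the measurement pass.
#' @return object of class `frame_assessment` with fields frame_id,
#'   adequate, reasons, geometry.
#' @export
assess_frame <- function(mask, adequacy = adequacy_thresholds(),
                         frame_id = NA_integer_,
                         config = geometry_config()) {
  reasons <- character(0)
  for (cl in adequacy$required_classes) {
    area <- sum(mask == cl)
    if (area == 0) reasons <- c(reasons, sprintf("MISSING_CLASS_%d", cl))
    else if (area < adequacy$min_class_area_px)
      reasons <- c(reasons, sprintf("SMALL_CLASS_%d", cl))
  }
  cfg <- config
  cfg$max_line_residual_px <- adequacy$max_line_residual_px
  cfg$max_circle_residual_px <- adequacy$max_circle_residual_px
  cfg$min_head_radius_px <- adequacy$min_head_radius_px
  geom <- measure(mask, cfg)
  if (!is.null(geom$baseline) && !is.null(geom$roof) &&
      "HIGH_LINE_RESIDUAL" %in% geom$quality_flags)
    reasons <- c(reasons, "HIGH_LINE_RESIDUAL")
  if (!is.null(geom$head)) {
    if ("HIGH_CIRCLE_RESIDUAL" %in% geom$quality_flags)
      reasons <- c(reasons, "HIGH_CIRCLE_RESIDUAL")
    if ("SMALL_HEAD" %in% geom$quality_flags)
      reasons <- c(reasons, "SMALL_HEAD")
  }
  if (length(reasons) == 0 && (is.na(geom$alpha_deg) || is.na(geom$fhc)))
    reasons <- c(reasons, "FIT_FAILED")
  structure(list(frame_id = frame_id, adequate = length(reasons) == 0,
                 reasons = reasons, geometry = geom),
            class = "frame_assessment")
}

#' Emulate the on-probe capture loop
#'
#' Scans frames in acquisition order, collecting adequate ones, and stops
#' as soon as `min_adequate_frames` have been captured (the operator would
#' then be notified the scan is complete).
#'
#' @param masks ordered list of label masks as acquired.
#' @param adequacy an [adequacy_thresholds()].
#' @param min_adequate_frames frames required for a complete capture.
#' @param config a [geometry_config()].
#' @return list with `captured_ids` (frame indices, acquisition order) and
#'   `complete` (logical).
#' @export
capture_loop <- function(masks, adequacy = adequacy_thresholds(),
                         min_adequate_frames = 5L,
                         config = geometry_config()) {
  check_scalar(min_adequate_frames, "min_adequate_frames", min = 1, integer = TRUE)
  captured <- integer(0)
  for (i in seq_along(masks)) {
    fa <- assess_frame(masks[[i]], adequacy, frame_id = i, config = config)
    if (fa$adequate) captured <- c(captured, i)
    if (length(captured) >= min_adequate_frames)
      return(list(captured_ids = captured, complete = TRUE))
  }
  list(captured_ids = captured, complete = FALSE)
}

#' Classify aggregated indices into the three-way decision
#'
#' `HEALTHY` iff `alpha_agg >= alpha_healthy_deg` and
#' `fhc_agg >= fhc_healthy` (boundary equality is healthy); otherwise
#' `FOLLOW_UP`. Inconclusiveness is decided upstream from frame adequacy,
#' not here.
#'
#' @param alpha_agg aggregated alpha angle (degrees).
#' @param fhc_agg aggregated femoral head coverage (fraction).
#' @param thresholds a [decision_thresholds()].
#' @return `"HEALTHY"` or `"FOLLOW_UP"`.
#' @export
classify <- function(alpha_agg, fhc_agg, thresholds = decision_thresholds()) {
  if (!is.finite(alpha_agg) || !is.finite(fhc_agg))
    hs_validation_error("aggregated indices must be finite")
  if (alpha_agg >= thresholds$alpha_healthy_deg &&
      fhc_agg >= thresholds$fhc_healthy) "HEALTHY" else "FOLLOW_UP"
}

#' Decide a full cine sweep
#'
#' Assesses every frame, gates on adequacy, aggregates the alpha angle and
#' coverage by the configured statistic (median) over adequate frames, and
#' classifies. Fewer than `min_adequate_frames` adequate frames yields
#' `INCONCLUSIVE` with absent aggregates. The complete per-frame audit
#' trail is retained.
#'
#' @param masks ordered list of label masks (at least one).
#' @param adequacy an [adequacy_thresholds()].
#' @param thresholds a [decision_thresholds()].
#' @param config a [geometry_config()].
#' @return object of class `sweep_decision` with label, alpha_agg_deg,
#'   fhc_agg, n_adequate, n_frames, frame_assessments.
#' @export
decide_sweep <- function(masks, adequacy = adequacy_thresholds(),
                         thresholds = decision_thresholds(),
                         config = geometry_config()) {
  if (length(masks) == 0)
    hs_validation_error("a sweep must contain at least one frame")
  fas <- lapply(seq_along(masks), function(i)
    assess_frame(masks[[i]], adequacy, frame_id = i, config = config))
  ok <- vapply(fas, `[[`, logical(1), "adequate")
  n_adequate <- sum(ok)
  if (n_adequate < thresholds$min_adequate_frames) {
    label <- "INCONCLUSIVE"; alpha_agg <- NA_real_; fhc_agg <- NA_real_
  } else {
    alphas <- vapply(fas[ok], function(f) f$geometry$alpha_deg, numeric(1))
    fhcs <- vapply(fas[ok], function(f) f$geometry$fhc, numeric(1))
    alpha_agg <- median(alphas)
    fhc_agg <- median(fhcs)
    label <- classify(alpha_agg, fhc_agg, thresholds)
  }
  structure(list(label = label, alpha_agg_deg = alpha_agg, fhc_agg = fhc_agg,
                 n_adequate = n_adequate, n_frames = length(masks),
                 frame_assessments = fas, thresholds = thresholds),
            class = "sweep_decision")
}

#' Serialize a sweep decision to JSON
#'
#' @param decision a `sweep_decision`.
#' @param path optional file to write.
#' @return JSON string (invisibly when `path` is given).
#' @export
decision_to_json <- function(decision, path = NULL) {
  frames <- lapply(decision$frame_assessments, function(f) list(
    frame_id = f$frame_id, adequate = f$adequate,
    reasons = as.list(f$reasons),
    alpha_deg = if (is.na(f$geometry$alpha_deg)) NULL else f$geometry$alpha_deg,
    fhc = if (is.na(f$geometry$fhc)) NULL else f$geometry$fhc))
  obj <- list(
    label = decision$label,
    alpha_agg_deg = if (is.na(decision$alpha_agg_deg)) NULL else decision$alpha_agg_deg,
    fhc_agg = if (is.na(decision$fhc_agg)) NULL else decision$fhc_agg,
    n_adequate = decision$n_adequate, n_frames = decision$n_frames,
    frames = frames)
  js <- jsonlite::toJSON(obj, auto_unbox = TRUE, digits = NA, null = "null")
  if (!is.null(path)) { writeLines(js, path); return(invisible(js)) }
  js
}

#' Plain-text one-page scan report
#'
#' Mirrors the app-style notification; display strings for the three
#' decisions are configurable (defaults: "Healthy", "FU Recommended",
#' "Inconclusive, Repeat Scan").
#'
#' @param decision a `sweep_decision`.
#' @param display named character vector mapping labels to display strings.
#' @param path optional file to write.
#' @return character vector of report lines (invisibly when `path` given).
#' @export
decision_report <- function(decision,
                            display = c(HEALTHY = "Healthy",
                                        FOLLOW_UP = "FU Recommended",
                                        INCONCLUSIVE = "Inconclusive, Repeat Scan"),
                            path = NULL) {
  fmt <- function(x, d) if (is.na(x)) "-" else formatC(x, digits = d, format = "f")
  lines <- c(
    "==== Hip screening scan report ====",
    sprintf("Decision: %s", display[[decision$label]]),
    sprintf("Adequate frames: %d of %d", decision$n_adequate, decision$n_frames),
    sprintf("Median alpha angle: %s deg", fmt(decision$alpha_agg_deg, 1)),
    sprintf("Median femoral head coverage: %s", fmt(decision$fhc_agg, 3)),
    "Per-frame assessment:",
    vapply(decision$frame_assessments, function(f) sprintf(
      "  frame %s: %s%s", as.character(f$frame_id),
      if (f$adequate) "adequate" else "inadequate",
      if (length(f$reasons)) paste0(" [", paste(f$reasons, collapse = ","), "]")
      else ""), character(1)))
  if (!is.null(path)) { writeLines(lines, path); return(invisible(lines)) }
  lines
}

#' @export
print.sweep_decision <- function(x, ...) {
  cat(decision_report(x), sep = "\n")
  invisible(x)
}
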