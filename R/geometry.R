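## Graf geometric measurement from label masks.
##
## The acetabular alpha angle is the angle at the bony rim between the iliac
## baseline and the bony-roof line; femoral head coverage (FHC) is the
## fraction of the head diameter medial to the baseline (Morin d/D). Both are
## computed from fitted primitives: total-least-squares lines through the
## two limbs of the class-1 (acetabulum-ilium) component and an algebraic
## least-squares circle through the class-2 (femoral head) boundary.

#' Geometry-fitting configuration
#'
#' @param max_line_residual_px RMS orthogonal residual above which a line fit
#'   is flagged `HIGH_LINE_RESIDUAL`. Bone strokes several pixels thick fit
#'   their center line with an RMS near width/sqrt(12), so the default
#'   tolerates a ~6 px stroke.
#' @param max_circle_residual_px RMS radial residual above which the head
#'   circle is flagged `HIGH_CIRCLE_RESIDUAL`.
#' @param min_roof_px minimum pixel support for the roof line.
#' @param min_circle_px minimum boundary pixel support for the head circle.
#' @param min_head_radius_px fitted radii below this raise `SMALL_HEAD`.
#' @param baseline_sep_px distance from the fitted baseline beyond which
#'   class-1 pixels are treated as roof support.
#' @param medial `"+col"` (default, the phantom convention: medial is toward
#'   increasing column) or `"-col"` for mirrored input.
#' @return list of class `geometry_config`.
#' @export
geometry_config <- function(max_line_residual_px = 2.5,
                            max_circle_residual_px = 2.0,
                            min_roof_px = 20, min_circle_px = 20,
                            min_head_radius_px = 8,
                            baseline_sep_px = 4.2,
                            medial = c("+col", "-col")) {
  medial <- match.arg(medial)
  structure(list(max_line_residual_px = max_line_residual_px,
                 max_circle_residual_px = max_circle_residual_px,
                 min_roof_px = min_roof_px, min_circle_px = min_circle_px,
                 min_head_radius_px = min_head_radius_px,
                 baseline_sep_px = baseline_sep_px, medial = medial),
            class = "geometry_config")
}

## Total least squares: principal axis of the point cloud. Returns point
## (centroid), unit direction, rms orthogonal residual, support size.
tls_line <- function(pts) {
  n <- nrow(pts)
  ctr <- colMeans(pts)
  X <- sweep(pts, 2, ctr)
  C <- crossprod(X) / n
  e <- eigen(C, symmetric = TRUE)
  dir <- e$vectors[, 1]
  dir <- dir / sqrt(sum(dir^2))
  resid <- X[, 1] * dir[2] - X[, 2] * dir[1]   # orthogonal distances
  structure(list(point = ctr, direction = dir,
                 rms_residual_px = sqrt(mean(resid^2)), n_support_px = n),
            class = "line_fit")
}

## TLS sum of squared orthogonal residuals from sufficient statistics.
tls_sse <- function(sx, sy, sxx, syy, sxy, n) {
  if (n < 2) return(0)
  cxx <- sxx / n - (sx / n)^2
  cyy <- syy / n - (sy / n)^2
  cxy <- sxy / n - (sx / n) * (sy / n)
  tr <- cxx + cyy
  det <- cxx * cyy - cxy^2
  lam_min <- tr / 2 - sqrt(max(tr^2 / 4 - det, 0))
  n * max(lam_min, 0)
}

dist_to_line <- function(pts, line) {
  d <- line$direction
  abs((pts[, 1] - line$point[1]) * d[2] - (pts[, 2] - line$point[2]) * d[1])
}

#' Fit the iliac baseline from a label mask
#'
#' The lateral edge of the largest class-1 component (per-row minimum
#' column) is split into two runs by an exhaustive two-segment
#' total-least-squares breakpoint search; the upper run is the iliac limb.
#' The final line is a TLS fit through the per-row midpoints of the iliac
#' stroke, which recovers the stroke's center line independently of its
#' width. The estimated stroke half-width is carried on the fit (field
#' `halfwidth_px`) so downstream support selection can scale with it.
#'
#' @param mask integer label matrix with labels in \{0, 1, 2\}.
#' @param config a [geometry_config()].
#' @return `line_fit` with fields point, direction (unit), rms_residual_px,
#'   n_support_px, halfwidth_px.
#' @export
fit_baseline <- function(mask, config = geometry_config()) {
  comp <- largest_component(mask == 1L)
  idx <- which(comp, arr.ind = TRUE)
  if (nrow(idx) == 0)
    hs_missing_landmark_error("class 1 (acetabulum-ilium) is empty")
  rows <- sort(unique(idx[, 1]))
  ## per-row lateral edge, and the contiguous stroke run starting there:
  ## its midpoint sits on the center line whatever the stroke width
  lat <- numeric(length(rows)); mid <- numeric(length(rows))
  len <- numeric(length(rows))
  for (i in seq_along(rows)) {
    cols <- sort(idx[idx[, 1] == rows[i], 2])
    lat[i] <- cols[1]
    run_end <- cols[1]
    for (cc in cols[-1]) { if (cc == run_end + 1) run_end <- cc else break }
    mid[i] <- (cols[1] + run_end) / 2
    len[i] <- run_end - cols[1] + 1
  }
  n <- length(rows)
  finish <- function(sel) {
    fit <- tls_line(cbind(rows[sel], mid[sel]))
    fit$halfwidth_px <- stats::median(len[sel]) / 2
    fit
  }
  if (n < 8) return(finish(seq_len(n)))
  ## breakpoint search on the lateral-edge profile locates the bony rim
  x <- rows; y <- lat
  cx <- cumsum(x); cy <- cumsum(y); cxx <- cumsum(x^2)
  cyy <- cumsum(y^2); cxy <- cumsum(x * y)
  tot <- function(a, b) {           # sse of points a..b (inclusive)
    if (b < a) return(0)
    m <- b - a + 1
    sx <- cx[b] - if (a > 1) cx[a - 1] else 0
    sy <- cy[b] - if (a > 1) cy[a - 1] else 0
    sxx <- cxx[b] - if (a > 1) cxx[a - 1] else 0
    syy <- cyy[b] - if (a > 1) cyy[a - 1] else 0
    sxy <- cxy[b] - if (a > 1) cxy[a - 1] else 0
    tls_sse(sx, sy, sxx, syy, sxy, m)
  }
  ks <- 3:(n - 1)
  sses <- vapply(ks, function(k) tot(1, k) + tot(k + 1, n), numeric(1))
  k_best <- ks[which.min(sses)]
  ## drop the rows just above the rim where baseline and roof merge
  finish(seq_len(max(3, k_best - 2)))
}

#' Fit the bony acetabular roof line
#'
#' Class-1 pixels of the largest component lying beyond
#' `baseline_sep_px` of the fitted baseline form the roof limb; a total
#' least-squares line is fitted through them.
#'
#' @inheritParams fit_baseline
#' @param baseline a `line_fit` from [fit_baseline()].
#' @return `line_fit`.
#' @export
fit_roof_line <- function(mask, baseline, config = geometry_config()) {
  comp <- largest_component(mask == 1L)
  idx <- which(comp, arr.ind = TRUE)
  if (nrow(idx) == 0)
    hs_missing_landmark_error("class 1 (acetabulum-ilium) is empty")
  hw <- baseline$halfwidth_px
  sep <- if (is.null(hw)) config$baseline_sep_px else
    max(config$baseline_sep_px, 1.6 * hw + 1)
  roof <- idx[dist_to_line(idx, baseline) > sep, , drop = FALSE]
  if (nrow(roof) < config$min_roof_px)
    hs_missing_landmark_error(sprintf(
      "roof support has %d px, below the minimum of %d", nrow(roof),
      config$min_roof_px))
  tls_line(roof)
}

#' Fit the femoral head circle
#'
#' Algebraic (Kasa) least-squares circle through the boundary pixels of the
#' largest class-2 component.
#'
#' @inheritParams fit_baseline
#' @return `circle_fit` with center, radius_px, rms_residual_px,
#'   n_support_px.
#' @export
fit_head_circle <- function(mask, config = geometry_config()) {
  comp <- largest_component(mask == 2L)
  if (!any(comp))
    hs_missing_landmark_error("class 2 (femoral head) is empty")
  ## boundary: component pixels with a 4-neighbor outside the component
  H <- nrow(comp); W <- ncol(comp)
  pad <- matrix(FALSE, H + 2, W + 2); pad[2:(H + 1), 2:(W + 1)] <- comp
  interior <- pad[1:H, 2:(W + 1)] & pad[3:(H + 2), 2:(W + 1)] &
    pad[2:(H + 1), 1:W] & pad[2:(H + 1), 3:(W + 2)]
  boundary <- comp & !interior
  pts <- which(boundary, arr.ind = TRUE)
  if (nrow(pts) < config$min_circle_px)
    hs_missing_landmark_error(sprintf(
      "head boundary has %d px, below the minimum of %d", nrow(pts),
      config$min_circle_px))
  x <- pts[, 1]; y <- pts[, 2]
  A <- cbind(2 * x, 2 * y, 1)
  bb <- x^2 + y^2
  sol <- qr.solve(A, bb)
  center <- sol[1:2]
  radius <- sqrt(max(sol[3] + sum(center^2), 1e-12))
  d <- sqrt((x - center[1])^2 + (y - center[2])^2)
  structure(list(center = as.numeric(center), radius_px = radius,
                 rms_residual_px = sqrt(mean((d - radius)^2)),
                 n_support_px = nrow(pts)),
            class = "circle_fit")
}

canonical_dirs <- function(baseline, roof, medial_sign) {
  b <- baseline$direction
  if (b[1] < 0) b <- -b                   # baseline points inferiorly
  u <- roof$direction
  if (u[2] * medial_sign < 0) u <- -u     # roof points medially
  list(b = b, u = u)
}

#' Acetabular alpha angle between baseline and roof line
#'
#' The angle at the rim between the baseline direction pointing inferiorly
#' and the roof direction pointing medially, in degrees. Invariant to sign
#' flips of either fitted direction vector. Near-parallel configurations
#' (< 1 degree) raise a degenerate-configuration error rather than
#' returning a silent value.
#'
#' @param baseline,roof `line_fit` objects.
#' @param config a [geometry_config()] (supplies the medial convention).
#' @return angle in degrees, in (0, 120\].
#' @export
alpha_angle <- function(baseline, roof, config = geometry_config()) {
  med <- if (config$medial == "+col") 1 else -1
  d <- canonical_dirs(baseline, roof, med)
  ang <- acos(pmin(1, pmax(-1, sum(d$b * d$u)))) * 180 / pi
  if (ang < 1)
    hs_degenerate_error(sprintf(
      "baseline and roof are near-parallel (angle %.3f deg)", ang))
  ang
}

#' Femoral head coverage from fitted circle and baseline
#'
#' Diameter-fraction coverage `clip((r + s) / (2 r), 0, 1)` with `s` the
#' signed distance from the head center to the baseline, positive on the
#' medial (covered) side.
#'
#' @param head a `circle_fit`.
#' @param baseline a `line_fit`.
#' @param config a [geometry_config()].
#' @return coverage fraction in \[0, 1\].
#' @export
femoral_head_coverage <- function(head, baseline, config = geometry_config()) {
  r <- head$radius_px
  if (!is.finite(r) || r <= 0)
    hs_validation_error("head radius must be positive")
  d <- baseline$direction
  nrm <- c(-d[2], d[1])
  med <- if (config$medial == "+col") 1 else -1
  if (nrm[2] * med < 0) nrm <- -nrm       # normal points medially
  s <- sum((head$center - baseline$point) * nrm)
  clip01((r + s) / (2 * r))
}

#' Measure Graf indices from a label mask
#'
#' Runs baseline, roof and head fits and derives the alpha angle and
#' femoral head coverage. Missing landmarks or degenerate fits never raise:
#' the affected index is absent (`NA`) and `quality_flags` explains why
#' (`MISSING_CLASS`, `HIGH_LINE_RESIDUAL`, `HIGH_CIRCLE_RESIDUAL`,
#' `SMALL_HEAD`, `DEGENERATE_ANGLE`).
#'
#' @inheritParams fit_baseline
#' @return object of class `hip_geometry` with fields alpha_deg, fhc,
#'   baseline, roof, head, quality_flags.
#' @export
measure <- function(mask, config = geometry_config()) {
  flags <- character(0)
  baseline <- tryCatch(fit_baseline(mask, config),
                       hipscreen_missing_landmark_error = function(e) NULL)
  roof <- if (!is.null(baseline))
    tryCatch(fit_roof_line(mask, baseline, config),
             hipscreen_missing_landmark_error = function(e) NULL) else NULL
  head_fit <- tryCatch(fit_head_circle(mask, config),
                       hipscreen_missing_landmark_error = function(e) NULL)

  if (is.null(baseline) || is.null(roof) || is.null(head_fit))
    flags <- c(flags, "MISSING_CLASS")
  for (ln in list(baseline, roof))
    if (!is.null(ln) && ln$rms_residual_px > config$max_line_residual_px)
      flags <- unique(c(flags, "HIGH_LINE_RESIDUAL"))
  if (!is.null(head_fit)) {
    if (head_fit$rms_residual_px > config$max_circle_residual_px)
      flags <- c(flags, "HIGH_CIRCLE_RESIDUAL")
    if (head_fit$radius_px < config$min_head_radius_px)
      flags <- c(flags, "SMALL_HEAD")
  }

  alpha <- NA_real_
  if (!is.null(baseline) && !is.null(roof)) {
    alpha <- tryCatch(alpha_angle(baseline, roof, config),
                      hipscreen_degenerate_error = function(e) {
                        flags <<- c(flags, "DEGENERATE_ANGLE"); NA_real_
                      })
  }
  fhc <- NA_real_
  if (!is.null(baseline) && !is.null(head_fit))
    fhc <- femoral_head_coverage(head_fit, baseline, config)

  structure(list(alpha_deg = alpha, fhc = fhc, baseline = baseline,
                 roof = roof, head = head_fit, quality_flags = flags),
            class = "hip_geometry")
}

#' Serialize a hip_geometry to JSON
#'
#' @param geom a `hip_geometry`.
#' @param path optional file to write.
#' @return JSON string (invisibly when `path` is given).
#' @export
geometry_to_json <- function(geom, path = NULL) {
  ser_line <- function(l) if (is.null(l)) NULL else
    list(point = l$point, direction = l$direction,
         rms_residual_px = l$rms_residual_px, n_support_px = l$n_support_px)
  obj <- list(
    alpha_deg = if (is.na(geom$alpha_deg)) NULL else geom$alpha_deg,
    fhc = if (is.na(geom$fhc)) NULL else geom$fhc,
    baseline = ser_line(geom$baseline), roof = ser_line(geom$roof),
    head = if (is.null(geom$head)) NULL else
      list(center = geom$head$center, radius_px = geom$head$radius_px,
           rms_residual_px = geom$head$rms_residual_px,
           n_support_px = geom$head$n_support_px),
    quality_flags = geom$quality_flags)
  js <- jsonlite::toJSON(obj, auto_unbox = TRUE, digits = NA, null = "null")
  if (!is.null(path)) { writeLines(js, path); return(invisible(js)) }
  js
}
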