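## Synthetic coronal Graf-plane hip phantom.
##
## Coordinate convention (used by every module): 0-based concepts are avoided
## inside R; matrices are indexed (row, col) from the top-left, rows increase
## inferiorly (down the image) and columns increase medially. The iliac
## baseline is rendered near-vertical; the bony acetabular roof leaves the
## rim point medially at the requested alpha angle; the femoral head is a
## hypoechoic disk whose signed offset from the baseline sets coverage.

STROKE_HALF_WIDTH <- 3      # bone echoes rendered 6 px wide
BG_LEVEL <- 0.35            # soft-tissue background intensity
BONE_LEVEL <- 0.92          # bright bone echo intensity
HEAD_LEVEL <- 0.08          # hypoechoic femoral head intensity
BASELINE_LEN <- 44          # iliac stroke length above the rim (px)
ROOF_LEN <- 48              # roof stroke length from the rim (px)

#' Specify a synthetic Graf-plane hip phantom
#'
#' A `phantom_spec` fully determines one synthetic hip: image size, the true
#' alpha angle between the iliac baseline and the bony roof, the femoral
#' head radius and its signed offset from the baseline (positive = medial,
#' i.e. covered side), and the corruption model (multiplicative speckle,
#' Gaussian blur, acoustic shadowing). Frames rendered more than
#' `adequate_band_px` away from the standard plane degrade: the femoral head
#' disappears and bone echo intensity decays linearly to zero.
#'
#' The true femoral head coverage implied by a spec is the diameter fraction
#' `clip((r + s) / (2 r), 0, 1)` with `r = head_radius_px` and
#' `s = head_offset_px`.
#'
#' @param image_height_px,image_width_px image dimensions in pixels.
#' @param alpha_true true alpha angle in degrees, in \[30, 90\].
#' @param head_radius_px femoral head radius in pixels (> 0).
#' @param head_offset_px signed displacement of the head center from the
#'   baseline along the baseline normal; positive is medial/covered.
#' @param speckle_strength variance of the unit-mean multiplicative gamma
#'   speckle factor (0 disables speckle).
#' @param blur_sigma_px Gaussian blur standard deviation in pixels.
#' @param shadow_strength intensity attenuation in \[0, 1\] applied below
#'   bone strokes.
#' @param rim_point (row, col) pixel coordinate where baseline and roof meet.
#' @param adequate_band_px absolute plane offset below which all landmarks
#'   render fully.
#' @param seed integer seed controlling the speckle field.
#' @return an object of class `phantom_spec`.
#' @export
#' @examples
#' spec <- phantom_spec(alpha_true = 65, head_offset_px = 6)
#' fr <- render_frame(spec)
#' fr$truth$fhc_true
phantom_spec <- function(image_height_px = 192, image_width_px = 160,
                         alpha_true = 65, head_radius_px = 24,
                         head_offset_px = 6, speckle_strength = 0.02,
                         blur_sigma_px = 0.8, shadow_strength = 0.1,
                         rim_point = c(48, 64), adequate_band_px = 6,
                         seed = 1L) {
  check_scalar(image_height_px, "image_height_px", min = 64, integer = TRUE)
  check_scalar(image_width_px, "image_width_px", min = 64, integer = TRUE)
  check_scalar(alpha_true, "alpha_true", min = 30, max = 90)
  check_scalar(head_radius_px, "head_radius_px", min = 1e-9)
  check_scalar(head_offset_px, "head_offset_px")
  check_scalar(speckle_strength, "speckle_strength", min = 0)
  check_scalar(blur_sigma_px, "blur_sigma_px", min = 0)
  check_scalar(shadow_strength, "shadow_strength", min = 0, max = 1)
  check_scalar(adequate_band_px, "adequate_band_px", min = 1e-9)
  check_scalar(seed, "seed", integer = TRUE)
  if (length(rim_point) != 2L || !all(is.finite(rim_point)))
    hs_validation_error("'rim_point' must be a finite (row, col) coordinate")
  if (abs(head_offset_px) > head_radius_px + 1e-9)
    hs_validation_error("'head_offset_px' must satisfy |offset| <= head_radius_px")

  spec <- structure(list(
    image_height_px = as.integer(image_height_px),
    image_width_px = as.integer(image_width_px),
    alpha_true = alpha_true, head_radius_px = head_radius_px,
    head_offset_px = head_offset_px, speckle_strength = speckle_strength,
    blur_sigma_px = blur_sigma_px, shadow_strength = shadow_strength,
    rim_point = as.numeric(rim_point), adequate_band_px = adequate_band_px,
    seed = as.integer(seed)
  ), class = "phantom_spec")

  geo <- phantom_geometry(spec)
  r <- head_radius_px
  ctr <- geo$head_center
  if (ctr[1] + r > image_height_px - 2 || ctr[2] + r > image_width_px - 2 ||
      ctr[2] - r < 2)
    hs_validation_error(
      "'head_radius_px'/'rim_point': femoral head does not fit in the image")
  spec
}

## Analytic construction: baseline direction, roof direction, head center.
phantom_geometry <- function(spec) {
  a <- spec$alpha_true * pi / 180
  d_base <- c(1, 0)                       # down the image (inferior)
  d_roof <- c(cos(a), sin(a))             # inferior-medial at alpha from base
  n_med <- c(0, 1)                        # baseline normal, medial side
  r <- spec$head_radius_px
  s <- spec$head_offset_px
  ## Depth below the rim chosen so the head disk clears the roof line.
  depth <- max(r + 10, (r + 4 + cos(a) * max(s, 0)) / sin(a))
  center <- spec$rim_point + depth * d_base + s * n_med
  list(d_base = d_base, d_roof = d_roof, n_med = n_med, head_center = center)
}

fhc_from_spec <- function(spec) {
  clip01((spec$head_radius_px + spec$head_offset_px) / (2 * spec$head_radius_px))
}

## Pixels within half-width of the segment p -> p + len * u (vectorized over
## a bounding box).
rasterize_stroke <- function(H, W, p, u, len, half_width) {
  q <- p + len * u
  r0 <- max(1, floor(min(p[1], q[1]) - half_width - 1))
  r1 <- min(H, ceiling(max(p[1], q[1]) + half_width + 1))
  c0 <- max(1, floor(min(p[2], q[2]) - half_width - 1))
  c1 <- min(W, ceiling(max(p[2], q[2]) + half_width + 1))
  if (r0 > r1 || c0 > c1) return(NULL)
  rows <- r0:r1; cols <- c0:c1
  rr <- matrix(rows, length(rows), length(cols))
  cc <- matrix(cols, length(rows), length(cols), byrow = TRUE)
  t_par <- (rr - p[1]) * u[1] + (cc - p[2]) * u[2]
  t_par <- pmin(pmax(t_par, 0), len)
  dr <- rr - (p[1] + t_par * u[1])
  dc <- cc - (p[2] + t_par * u[2])
  hit <- (dr * dr + dc * dc) <= half_width^2
  list(rows = rows, cols = cols, hit = hit)
}

apply_region <- function(mat, reg, value) {
  if (is.null(reg)) return(mat)
  sub <- mat[reg$rows, reg$cols, drop = FALSE]
  sub[reg$hit] <- value
  mat[reg$rows, reg$cols] <- sub
  mat
}

rasterize_disk <- function(H, W, center, radius) {
  r0 <- max(1, floor(center[1] - radius)); r1 <- min(H, ceiling(center[1] + radius))
  c0 <- max(1, floor(center[2] - radius)); c1 <- min(W, ceiling(center[2] + radius))
  rows <- r0:r1; cols <- c0:c1
  rr <- matrix(rows, length(rows), length(cols))
  cc <- matrix(cols, length(rows), length(cols), byrow = TRUE)
  hit <- (rr - center[1])^2 + (cc - center[2])^2 <= radius^2
  list(rows = rows, cols = cols, hit = hit)
}

#' Render one phantom frame with its exact ground truth
#'
#' Draws the iliac baseline stroke, the bony-roof stroke leaving the rim at
#' the true alpha angle, and the hypoechoic femoral head disk; then applies
#' out-of-plane degradation, acoustic shadowing, multiplicative speckle and
#' Gaussian blur. The returned ground truth carries the analytic
#' construction (lines, head circle, alpha, coverage) and the clean label
#' mask (0 = background, 1 = acetabulum-ilium complex, 2 = femoral head).
#'
#' Frames with `|plane_offset| <= adequate_band_px` render all landmarks at
#' full contrast; past the band the femoral head is absent and bone echo
#' intensity decays linearly, reaching zero at twice the band.
#'
#' Rendering is deterministic: identical (spec, plane_offset) pairs yield
#' bit-identical frames.
#'
#' @param spec a [phantom_spec()].
#' @param plane_offset signed out-of-plane displacement in pixels
#'   (0 = standard plane).
#' @return list with `image` (numeric matrix in \[0, 1\]) and `truth`
#'   (class `ground_truth`: `label_mask`, `alpha_true`, `fhc_true`,
#'   `baseline_true`, `roof_true`, `head_center_true`, `head_radius_true`,
#'   `plane_offset`).
#' @export
render_frame <- function(spec, plane_offset = 0) {
  if (!inherits(spec, "phantom_spec"))
    hs_validation_error("'spec' must be a phantom_spec")
  check_scalar(plane_offset, "plane_offset")
  H <- spec$image_height_px; W <- spec$image_width_px
  geo <- phantom_geometry(spec)
  band <- spec$adequate_band_px
  off <- abs(plane_offset)
  in_band <- off <= band
  fade <- if (in_band) 1 else max(0, 1 - (off - band) / band)

  base_start <- spec$rim_point - min(spec$rim_point[1] - 4, BASELINE_LEN) * geo$d_base
  base_len <- min(spec$rim_point[1] - 4, BASELINE_LEN)
  roof_len <- ROOF_LEN

  mask <- matrix(0L, H, W)
  img <- matrix(BG_LEVEL, H, W)

  if (fade > 0) {
    reg_base <- rasterize_stroke(H, W, base_start, geo$d_base, base_len,
                                 STROKE_HALF_WIDTH)
    reg_roof <- rasterize_stroke(H, W, spec$rim_point, geo$d_roof, roof_len,
                                 STROKE_HALF_WIDTH)
    bone_val <- BG_LEVEL + (BONE_LEVEL - BG_LEVEL) * fade
    img <- apply_region(img, reg_base, bone_val)
    img <- apply_region(img, reg_roof, bone_val)
    mask <- apply_region(mask, reg_base, 1L)
    mask <- apply_region(mask, reg_roof, 1L)
  }
  if (in_band) {
    reg_head <- rasterize_disk(H, W, geo$head_center, spec$head_radius_px)
    img <- apply_region(img, reg_head, HEAD_LEVEL)
    mask <- apply_region(mask, reg_head, 2L)
  }

  ## Acoustic shadow: attenuate everything strictly below bone in a column.
  if (spec$shadow_strength > 0 && fade > 0) {
    att <- matrix(1, H, W)
    bone_cols <- which(colSums(mask == 1L) > 0)
    for (cc in bone_cols) {
      last <- max(which(mask[, cc] == 1L))
      if (last < H) att[(last + 1):H, cc] <- 1 - spec$shadow_strength * fade
    }
    img <- img * att
  }

  if (spec$speckle_strength > 0) {
    seed_used <- (spec$seed * 131L + as.integer(round(plane_offset * 97))) %% 2147483647L
    withr::with_seed(seed_used, {
      v <- spec$speckle_strength
      fac <- matrix(rgamma(H * W, shape = 1 / v, scale = v), H, W)
      img <- img * fac
    })
  }
  img <- gaussian_blur(img, spec$blur_sigma_px)
  img <- clip01(img)

  truth <- structure(list(
    label_mask = mask,
    alpha_true = spec$alpha_true,
    fhc_true = fhc_from_spec(spec),
    baseline_true = list(point = spec$rim_point, direction = geo$d_base),
    roof_true = list(point = spec$rim_point, direction = geo$d_roof),
    head_center_true = geo$head_center,
    head_radius_true = spec$head_radius_px,
    plane_offset = plane_offset
  ), class = "ground_truth")

  list(image = img, truth = truth)
}

#' Specify a cine sweep over one phantom
#'
#' @param phantom a [phantom_spec()].
#' @param plane_offsets signed plane offsets (px), one per frame, in
#'   acquisition order; 0 is the standard plane.
#' @param adequate_band_px adequacy band; defaults to the phantom's.
#' @return object of class `sweep_spec`.
#' @export
sweep_spec <- function(phantom, plane_offsets,
                       adequate_band_px = phantom$adequate_band_px) {
  if (!inherits(phantom, "phantom_spec"))
    hs_validation_error("'phantom' must be a phantom_spec")
  if (length(plane_offsets) > 0 && !all(is.finite(plane_offsets)))
    hs_validation_error("'plane_offsets' must be finite")
  check_scalar(adequate_band_px, "adequate_band_px", min = 1e-9)
  phantom$adequate_band_px <- adequate_band_px
  structure(list(phantom = phantom, n_frames = length(plane_offsets),
                 plane_offsets = as.numeric(plane_offsets),
                 adequate_band_px = adequate_band_px),
            class = "sweep_spec")
}

#' Render an ordered cine sweep
#'
#' @param sweep a [sweep_spec()].
#' @return list with `frames` (list of image matrices) and `truths`
#'   (list of `ground_truth`), both in acquisition order.
#' @export
render_sweep <- function(sweep) {
  if (!inherits(sweep, "sweep_spec"))
    hs_validation_error("'sweep' must be a sweep_spec")
  out <- lapply(sweep$plane_offsets, function(o) render_frame(sweep$phantom, o))
  list(frames = lapply(out, `[[`, "image"),
       truths = lapply(out, `[[`, "truth"))
}

#' Generate a multi-subject phantom dataset
#'
#' Draws per-subject hip geometry uniformly from the requested alpha and
#' coverage ranges (head radius and rim position are mildly jittered to vary
#' scale and framing), then renders `frames_per_subject` near-standard-plane
#' frames per subject with the spec's default corruption model. Intended as
#' the training and evaluation corpus for the segmentation module.
#'
#' @param n_subjects number of subjects (>= 1).
#' @param alpha_range degree interval for the true alpha angle, within
#'   \[30, 90\].
#' @param fhc_range interval for the true femoral head coverage, within
#'   \[0, 1\].
#' @param frames_per_subject frames rendered per subject.
#' @param seed integer seed; identical calls reproduce the dataset exactly.
#' @param speckle_strength,blur_sigma_px,shadow_strength corruption model
#'   passed to every subject's [phantom_spec()].
#' @return list with `images`, `masks` (parallel lists), `truth` (data.frame
#'   with subject_id, frame_id, alpha_true_deg, fhc_true, plane_offset_px,
#'   seed) and `subject_ids`.
#' @export
make_dataset <- function(n_subjects, alpha_range = c(45, 80),
                         fhc_range = c(0.3, 0.85), frames_per_subject = 4,
                         seed = 1L, speckle_strength = 0.02,
                         blur_sigma_px = 0.8, shadow_strength = 0.1) {
  check_scalar(n_subjects, "n_subjects", min = 1, integer = TRUE)
  check_scalar(frames_per_subject, "frames_per_subject", min = 1, integer = TRUE)
  check_scalar(seed, "seed", integer = TRUE)
  if (length(alpha_range) != 2L || diff(alpha_range) < 0 ||
      alpha_range[1] < 30 || alpha_range[2] > 90)
    hs_validation_error("'alpha_range' must be a non-empty interval within [30, 90]")
  if (length(fhc_range) != 2L || diff(fhc_range) < 0 ||
      fhc_range[1] < 0 || fhc_range[2] > 1)
    hs_validation_error("'fhc_range' must be a non-empty interval within [0, 1]")

  images <- list(); masks <- list(); rows <- list()
  withr::with_seed(seed, {
    for (si in seq_len(n_subjects)) {
      subject_id <- sprintf("S%03d", si)
      alpha <- runif(1, alpha_range[1], alpha_range[2])
      fhc <- runif(1, fhc_range[1], fhc_range[2])
      radius <- runif(1, 20, 28)
      rim <- c(48 + runif(1, -6, 6), 64 + runif(1, -6, 6))
      sub_seed <- (seed * 7919L + si * 104729L) %% 2147483647L
      spec <- phantom_spec(alpha_true = alpha, head_radius_px = radius,
                           head_offset_px = (2 * fhc - 1) * radius,
                           rim_point = rim, seed = sub_seed,
                           speckle_strength = speckle_strength,
                           blur_sigma_px = blur_sigma_px,
                           shadow_strength = shadow_strength)
      offsets <- runif(frames_per_subject, -spec$adequate_band_px / 2,
                       spec$adequate_band_px / 2)
      for (fi in seq_len(frames_per_subject)) {
        fr <- render_frame(spec, offsets[fi])
        k <- length(images) + 1L
        images[[k]] <- fr$image
        masks[[k]] <- fr$truth$label_mask
        rows[[k]] <- data.frame(
          subject_id = subject_id, frame_id = sprintf("%s_F%02d", subject_id, fi),
          alpha_true_deg = alpha, fhc_true = fhc,
          plane_offset_px = offsets[fi], seed = seed,
          stringsAsFactors = FALSE)
      }
    }
  })
  truth <- do.call(rbind, rows)
  list(images = images, masks = masks, truth = truth,
       subject_ids = unique(truth$subject_id))
}
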