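## Shared fixtures and independent oracles for the test suite. Everything
## here is deliberately simple and written independently of the package's
## own code paths, so it can serve as a brute-force reference.

## Rasterize a filled disk into a label mask.
disk_mask <- function(H, W, center, radius, class_id = 2L) {
  m <- matrix(0L, H, W)
  for (r in seq_len(H)) for (cc in seq_len(W))
    if ((r - center[1])^2 + (cc - center[2])^2 <= radius^2)
      m[r, cc] <- class_id
  m
}

## Nearest-neighbor rotation of a label mask about the image center
## (inverse mapping, so no holes).
rotate_mask <- function(mask, theta_deg) {
  H <- nrow(mask); W <- ncol(mask)
  th <- theta_deg * pi / 180
  ctr <- c((H + 1) / 2, (W + 1) / 2)
  out <- matrix(0L, H, W)
  for (r in seq_len(H)) {
    dr <- r - ctr[1]
    for (cc in seq_len(W)) {
      dc <- cc - ctr[2]
      sr <- round(ctr[1] + cos(th) * dr + sin(th) * dc)
      sc <- round(ctr[2] - sin(th) * dr + cos(th) * dc)
      if (sr >= 1 && sr <= H && sc >= 1 && sc <= W) out[r, cc] <- mask[sr, sc]
    }
  }
  out
}

## Brute-force DICE loss oracle: explicit per-pixel accumulation, smoothing
## constant 1, mean over foreground classes 1 and 2.
dice_loss_oracle <- function(pred, truth) {
  eps <- 1.0
  total <- 0
  for (k in 1:2) {
    num <- 0; sp <- 0; st <- 0
    for (i in seq_len(nrow(truth))) for (j in seq_len(ncol(truth))) {
      p <- pred[i, j, k + 1]
      t <- as.numeric(truth[i, j] == k)
      num <- num + p * t; sp <- sp + p; st <- st + t
    }
    total <- total + (2 * num + eps) / (sp + st + eps)
  }
  1 - total / 2
}

## Random soft probability field (per-pixel simplex) and random label mask.
random_pred <- function(H, W, seed) {
  withr::with_seed(seed, {
    a <- array(runif(H * W * 3), c(H, W, 3))
    s <- a[, , 1] + a[, , 2] + a[, , 3]
    for (k in 1:3) a[, , k] <- a[, , k] / s
    a
  })
}

random_truth <- function(H, W, seed) {
  withr::with_seed(seed, matrix(sample(0:2, H * W, replace = TRUE), H, W))
}

## Pixel-count coverage oracle: extreme-point projection of rasterized disk
## pixels onto the medial axis, as a fraction of the projected diameter.
coverage_pixel_oracle <- function(center, radius, baseline_col, H = 256, W = 256) {
  m <- disk_mask(H, W, center, radius)
  cols <- which(m == 2L, arr.ind = TRUE)[, 2]
  medial <- max(cols) - baseline_col
  max(0, min(1, medial / (max(cols) - min(cols))))
}

## A phantom spec with all corruption disabled (exact rendering).
clean_spec <- function(alpha, fhc, radius = 24, seed = 1, ...) {
  phantom_spec(alpha_true = alpha, head_radius_px = radius,
               head_offset_px = (2 * fhc - 1) * radius,
               speckle_strength = 0, blur_sigma_px = 0, shadow_strength = 0,
               seed = seed, ...)
}

## Render a full cine sweep and reference-segment every frame.
segmented_sweep <- function(alpha, fhc, offsets, seed = 1, radius = 24) {
  spec <- phantom_spec(alpha_true = alpha, head_radius_px = radius,
                       head_offset_px = (2 * fhc - 1) * radius, seed = seed)
  sw <- render_sweep(sweep_spec(spec, offsets))
  lapply(sw$frames, reference_segment)
}
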