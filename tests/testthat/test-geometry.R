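# Graf geometry: line/circle fitting accuracy, the alpha angle and
# coverage formulas, invariances, and the quality-flag contract.

test_that("baseline fit recovers an exact vertical segment", {
  m <- matrix(0L, 120, 100)
  m[10:70, 40] <- 1L
  fit <- fit_baseline(m)
  ang_from_vertical <- acos(abs(fit$direction[1])) * 180 / pi
  expect_lt(ang_from_vertical, 0.1)
  expect_lt(fit$rms_residual_px, 0.5)
  expect_error(fit_baseline(matrix(0L, 20, 20)),
               class = "hipscreen_missing_landmark_error")
})

test_that("baseline fit direction is rotation-equivariant", {
  mask <- render_frame(clean_spec(60, 0.6))$truth$label_mask
  base0 <- fit_baseline(mask)
  for (theta in c(-10, 10)) {
    rot <- rotate_mask(mask, theta)
    fit <- fit_baseline(rot)
    d0 <- base0$direction; d1 <- fit$direction
    dang <- acos(pmin(1, abs(sum(d0 * d1)))) * 180 / pi
    expect_lt(abs(dang - abs(theta)), 0.2)
  }
})

test_that("roof line meets the baseline at the constructed alpha", {
  mask <- render_frame(clean_spec(60, 0.6))$truth$label_mask
  base <- fit_baseline(mask)
  roof <- fit_roof_line(mask, base)
  expect_lt(abs(alpha_angle(base, roof) - 60), 1)

  ## recovered angles are monotone in the construction angle
  rec <- vapply(c(40, 50, 60, 70), function(a) {
    mk <- render_frame(clean_spec(a, 0.6))$truth$label_mask
    b <- fit_baseline(mk)
    alpha_angle(b, fit_roof_line(mk, b))
  }, numeric(1))
  expect_true(all(diff(rec) > 0))
})

test_that("a roof below the minimum support is a missing landmark", {
  m <- matrix(0L, 120, 100)
  m[10:70, 40] <- 1L
  m[71, 41:43] <- 1L       # 3 roof pixels, far fewer than the minimum
  base <- fit_baseline(m)
  expect_error(fit_roof_line(m, base, geometry_config(min_roof_px = 10)),
               class = "hipscreen_missing_landmark_error")
})

test_that("circle fit localizes an exact disk to within a pixel", {
  m <- disk_mask(200, 200, c(100, 120), 30)
  fit <- fit_head_circle(m)
  expect_lt(abs(fit$center[1] - 100), 1)
  expect_lt(abs(fit$center[2] - 120), 1)
  expect_lt(abs(fit$radius_px - 30), 1)
  expect_lt(fit$rms_residual_px, 0.7)
  expect_error(fit_head_circle(matrix(0L, 50, 50)),
               class = "hipscreen_missing_landmark_error")
})

test_that("alpha angle formula: perpendicular, analytic, degenerate, sign-flip", {
  mkline <- function(dir, pt = c(0, 0)) structure(
    list(point = pt, direction = dir / sqrt(sum(dir^2)),
         rms_residual_px = 0, n_support_px = 100), class = "line_fit")
  vert <- mkline(c(1, 0))
  horiz <- mkline(c(0, 1))
  expect_equal(alpha_angle(vert, horiz), 90)

  a <- 57.3 * pi / 180
  roof <- mkline(c(cos(a), sin(a)))
  expect_equal(alpha_angle(vert, roof), 57.3, tolerance = 1e-6)
  ## invariant to direction sign flips of either line
  expect_equal(alpha_angle(mkline(c(-1, 0)), mkline(-c(cos(a), sin(a)))),
               57.3, tolerance = 1e-6)

  expect_error(alpha_angle(vert, mkline(c(1, 0))),
               class = "hipscreen_degenerate_error")
})

test_that("coverage formula: symmetry, extremes, pixel oracle", {
  mkline <- function(dir, pt) structure(
    list(point = pt, direction = dir, rms_residual_px = 0,
         n_support_px = 100), class = "line_fit")
  mkcirc <- function(center, r) structure(
    list(center = center, radius_px = r, rms_residual_px = 0,
         n_support_px = 100), class = "circle_fit")
  base <- mkline(c(1, 0), c(0, 100))
  expect_equal(femoral_head_coverage(mkcirc(c(50, 100), 20), base), 0.5)
  expect_equal(femoral_head_coverage(mkcirc(c(50, 80), 20), base), 0.0)
  expect_equal(femoral_head_coverage(mkcirc(c(50, 110), 20), base), 0.75)
  expect_error(femoral_head_coverage(mkcirc(c(50, 110), -1), base),
               class = "hipscreen_validation_error")

  ## rasterized pixel-projection oracle, radii >= 20
  for (r in c(20, 25, 30)) for (s in c(-r / 2, 0, r / 3)) {
    got <- femoral_head_coverage(mkcirc(c(120, 100 + s), r), base)
    oracle <- coverage_pixel_oracle(c(120, 100 + s), r, baseline_col = 100)
    expect_lt(abs(got - oracle), 0.01)
  }
})

test_that("measure recovers phantom parameters and flags incomplete masks", {
  withr::with_seed(31, {
    errs_a <- errs_f <- numeric(12)
    for (i in 1:12) {
      a <- runif(1, 40, 75); f <- runif(1, 0.2, 0.8)
      fr <- render_frame(clean_spec(a, f, radius = runif(1, 20, 28), seed = i))
      g <- measure(fr$truth$label_mask)
      errs_a[i] <- abs(g$alpha_deg - a)
      errs_f[i] <- abs(g$fhc - f)
    }
    expect_lte(mean(errs_a), 2)
    expect_lte(mean(errs_f), 0.05)
  })

  mask <- render_frame(clean_spec(60, 0.6))$truth$label_mask
  headless <- mask; headless[headless == 2L] <- 0L
  g <- measure(headless)
  expect_true("MISSING_CLASS" %in% g$quality_flags)
  expect_true(is.na(g$fhc))
  expect_false(is.na(g$alpha_deg))     # lines still fit

  ## a tight residual bound flags the (thick-stroke) lines
  g2 <- measure(mask, geometry_config(max_line_residual_px = 0.1))
  expect_true("HIGH_LINE_RESIDUAL" %in% g2$quality_flags)

  ## measure never raises, even on an empty mask
  g3 <- measure(matrix(0L, 64, 64))
  expect_true("MISSING_CLASS" %in% g3$quality_flags)
  expect_true(is.na(g3$alpha_deg) && is.na(g3$fhc))
})

test_that("alpha and coverage are rotation-invariant to within tolerance", {
  mask <- render_frame(clean_spec(58, 0.55))$truth$label_mask
  g0 <- measure(mask)
  for (theta in c(-10, -5, 5, 10)) {
    g <- measure(rotate_mask(mask, theta))
    expect_lt(abs(g$alpha_deg - g0$alpha_deg), 1)
    expect_lt(abs(g$fhc - g0$fhc), 0.02)
  }
})

test_that("alpha and coverage are stable under 2x upsampling", {
  mask <- render_frame(clean_spec(62, 0.65))$truth$label_mask
  up <- mask[rep(seq_len(nrow(mask)), each = 2), rep(seq_len(ncol(mask)), each = 2)]
  g0 <- measure(mask)
  g2 <- measure(up)
  expect_lt(abs(g2$alpha_deg - g0$alpha_deg), 0.5)
  expect_lt(abs(g2$fhc - g0$fhc), 0.01)
})

test_that("hip geometry serializes to JSON with flags", {
  g <- measure(render_frame(clean_spec(60, 0.6))$truth$label_mask)
  js <- jsonlite::fromJSON(geometry_to_json(g))
  expect_equal(js$alpha_deg, g$alpha_deg)
  expect_equal(js$fhc, g$fhc)
  g2 <- measure(matrix(0L, 32, 32))
  js2 <- jsonlite::fromJSON(geometry_to_json(g2))
  expect_true("MISSING_CLASS" %in% js2$quality_flags)
})
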