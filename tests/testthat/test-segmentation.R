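# Preprocessing, DICE loss (with brute-force oracle), subject-disjoint
# splitting, and the deterministic reference segmenter.

test_that("preprocess normalizes to unit mean and resizes", {
  const <- matrix(0.4, 100, 80)
  out <- preprocess(const, 64)
  expect_equal(dim(out), c(64, 64))
  expect_true(all(abs(out - 1) < 1e-9))

  sized <- matrix(runif(64 * 64), 64, 64)
  sized <- sized / mean(sized)
  expect_equal(preprocess(sized, 64), sized)          # no resample, exact
  expect_equal(preprocess(preprocess(sized, 64), 64), sized)

  big <- matrix(runif(512 * 512), 512, 512)
  out2 <- preprocess(big, 256)
  expect_equal(dim(out2), c(256, 256))
  expect_lt(abs(mean(out2) - 1), 1e-3)
})

test_that("preprocess rejects degenerate input", {
  expect_error(preprocess(matrix(0, 10, 10)),
               class = "hipscreen_validation_error")
  expect_error(preprocess(matrix(c(NA, 1), 2, 2)),
               class = "hipscreen_validation_error")
})

test_that("dice_loss identities: perfect, disjoint, half-overlap", {
  H <- 40; W <- 40
  truth <- matrix(0L, H, W); truth[5:14, 5:24] <- 1L; truth[25:34, 5:24] <- 2L
  onehot <- array(0, c(H, W, 3))
  for (k in 0:2) onehot[, , k + 1] <- (truth == k) * 1
  expect_lt(dice_loss(onehot, truth), 1e-2)   # eps keeps it slightly above 0
  expect_lt(dice_loss(onehot, truth), dice_loss(array(1 / 3, c(H, W, 3)), truth))

  ## prediction foreground disjoint from truth foreground, both non-empty
  shifted <- array(0, c(H, W, 3)); shifted[, , 1] <- 1
  shifted[15:24, 30:39, 2] <- 1; shifted[15:24, 30:39, 1] <- 0
  shifted[30:39, 1:10, 3] <- 1; shifted[30:39, 1:10, 1] <- 0
  truth_d <- matrix(0L, H, W)
  truth_d[1:10, 1:10] <- 1L; truth_d[1:10, 21:30] <- 2L
  expect_gt(dice_loss(shifted, truth_d), 0.99)

  ## hard prediction covering exactly half of one truth region, no false
  ## positives: per-class DICE 2*(A/2)/(A/2+A) = 2/3, loss for that class 1/3
  truth_h <- matrix(0L, H, W); truth_h[1:20, 1:20] <- 1L   # A = 400
  pred_h <- array(0, c(H, W, 3)); pred_h[, , 1] <- 1
  pred_h[1:10, 1:20, 2] <- 1; pred_h[1:10, 1:20, 1] <- 0   # A/2 = 200
  ## class 2 absent from both truth and pred: its smoothed DICE is 1
  got <- dice_loss(pred_h, truth_h)
  want <- 1 - mean(c((2 * 200 + 1) / (200 + 400 + 1), 1))
  expect_equal(got, want, tolerance = 1e-12)
  expect_equal(want, 1 - mean(c(2 / 3, 1)), tolerance = 1e-2)
})

test_that("dice_loss validates inputs", {
  expect_error(dice_loss(array(0.5, c(8, 8, 3)), matrix(0L, 9, 9)),
               class = "hipscreen_validation_error")
  expect_error(dice_loss(array(2, c(8, 8, 3)), matrix(0L, 8, 8)),
               class = "hipscreen_validation_error")
})

test_that("dice_loss matches the pixel-count brute force on random pairs", {
  for (i in 1:30) {
    pred <- random_pred(32, 32, seed = 1000 + i)
    truth <- random_truth(32, 32, seed = 2000 + i)
    expect_lt(abs(dice_loss(pred, truth) - dice_loss_oracle(pred, truth)),
              1e-6)
  }
})

test_that("grouped_split is subject-disjoint, proportional, deterministic", {
  truth <- data.frame(subject_id = rep(sprintf("S%02d", 1:10), each = 3))
  sp <- grouped_split(truth, seed = 4)
  expect_length(sp$train_subjects, 8)
  expect_length(sp$val_subjects, 2)
  expect_length(intersect(sp$train_subjects, sp$val_subjects), 0)
  expect_setequal(c(sp$train_ids, sp$val_ids), seq_len(30))
  sp2 <- grouped_split(truth, seed = 4)
  expect_identical(sp, sp2)

  ## unequal frame counts never leak a subject
  truth_uneq <- data.frame(
    subject_id = rep(c("A", "B", "C", "D", "E"), times = c(1, 7, 2, 9, 4)))
  for (seed in 1:20) {
    spu <- grouped_split(truth_uneq, seed = seed)
    leak <- intersect(unique(truth_uneq$subject_id[spu$train_ids]),
                      unique(truth_uneq$subject_id[spu$val_ids]))
    expect_length(leak, 0)
  }

  expect_error(grouped_split(data.frame(subject_id = "A")),
               class = "hipscreen_validation_error")
  expect_error(grouped_split(truth, fractions = c(train = 0.5, val = 0.2)),
               class = "hipscreen_validation_error")
})

test_that("reference segmenter recovers noise-free phantom masks (DICE >= 0.9)", {
  withr::with_seed(77, {
    for (i in 1:20) {
      spec <- clean_spec(runif(1, 40, 80), runif(1, 0.2, 0.8),
                         radius = runif(1, 20, 28), seed = i)
      fr <- render_frame(spec)
      got <- reference_segment(fr$image)
      d1 <- hipscreen:::hard_dice(got, fr$truth$label_mask, 1L)
      d2 <- hipscreen:::hard_dice(got, fr$truth$label_mask, 2L)
      expect_gte(d1, 0.9)
      expect_gte(d2, 0.9)
    }
  })
})

test_that("reference segmenter reports missing landmarks, not errors", {
  spec <- clean_spec(60, 0.6)
  far <- render_frame(spec, spec$adequate_band_px * 1.4)
  m <- reference_segment(far$image)
  expect_false(any(m == 2L))      # head invisible out of plane
  blank <- matrix(0.35, 64, 64)
  expect_equal(unique(as.vector(reference_segment(blank))), 0L)
})
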