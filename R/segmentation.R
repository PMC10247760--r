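## Landmark segmentation support: input normalization, the DICE loss used
## for training, subject-disjoint data splitting, and a deterministic
## intensity-and-morphology reference segmenter for phantom frames.

DICE_EPS <- 1.0  # smoothing constant, in pixel-count units

#' Normalize and resize an input frame
#'
#' Divides the image by its overall mean intensity (so the normalized image
#' has mean exactly 1 before resampling) and resizes to
#' `input_size x input_size` with bilinear interpolation. When the image is
#' already at the target size no resampling is performed, making the
#' operation idempotent on normalized, correctly sized input.
#'
#' @param image numeric matrix with finite values and positive mean.
#' @param input_size side length of the square network input in pixels.
#' @return numeric `input_size x input_size` matrix.
#' @export
preprocess <- function(image, input_size = 256) {
  if (!is.matrix(image) || length(image) == 0)
    hs_validation_error("'image' must be a non-empty matrix")
  if (!all(is.finite(image)))
    hs_validation_error("'image' must contain only finite values")
  m <- mean(image)
  if (m <= 0)
    hs_validation_error("degenerate input: image mean intensity is not positive")
  check_scalar(input_size, "input_size", min = 32, integer = TRUE)
  resize_bilinear(image / m, input_size, input_size)
}

#' Soft DICE loss over foreground classes
#'
#' `1 - mean_k (2 sum(p_k t_k) + eps) / (sum(p_k) + sum(t_k) + eps)` where
#' the mean runs over the two foreground classes (acetabulum-ilium complex
#' and femoral head; background is excluded so it cannot swamp the loss)
#' and `eps = 1` pixel smooths empty classes.
#'
#' @param pred H x W x 3 array of per-class probabilities in \[0, 1\]
#'   (class order: background, acetabulum, head).
#' @param truth integer label matrix with labels in \{0, 1, 2\}.
#' @return scalar loss in \[0, 1\].
#' @export
dice_loss <- function(pred, truth) {
  if (length(dim(pred)) != 3L || dim(pred)[3] < 3L)
    hs_validation_error("'pred' must be an H x W x 3 probability array")
  if (!all(dim(pred)[1:2] == dim(truth)))
    hs_validation_error("prediction and truth dimensions differ")
  if (min(pred) < -1e-9 || max(pred) > 1 + 1e-9)
    hs_validation_error("'pred' probabilities must lie in [0, 1]")
  d <- vapply(1:2, function(k) {
    p <- pred[, , k + 1]
    t <- (truth == k) * 1
    (2 * sum(p * t) + DICE_EPS) / (sum(p) + sum(t) + DICE_EPS)
  }, numeric(1))
  1 - mean(d)
}

## Hard per-class DICE (2|A n B| / (|A| + |B|)); both empty -> 1.
hard_dice <- function(pred_mask, truth_mask, class_id) {
  a <- pred_mask == class_id
  b <- truth_mask == class_id
  denom <- sum(a) + sum(b)
  if (denom == 0) return(1)
  2 * sum(a & b) / denom
}

#' Subject-disjoint train/validation split
#'
#' Frames are partitioned at the subject level so no subject contributes to
#' both sets (the strictest of image/study/patient disjointness, which for
#' one-study-per-subject data implies the others). Subject counts follow
#' the requested fractions to within one subject.
#'
#' @param dataset a list with a `truth` data.frame carrying `subject_id`
#'   per frame (as from [make_dataset()]), or any data.frame with a
#'   `subject_id` column.
#' @param fractions named numeric `c(train = , val = )` summing to 1.
#' @param seed integer seed; identical seeds reproduce the split.
#' @return list with `train_ids` and `val_ids` (frame indices) plus
#'   `train_subjects`, `val_subjects`.
#' @export
grouped_split <- function(dataset, fractions = c(train = 0.8, val = 0.2),
                          seed = 1L) {
  truth <- if (is.data.frame(dataset)) dataset else dataset$truth
  if (is.null(truth$subject_id))
    hs_validation_error("every frame must carry a subject_id")
  if (abs(sum(fractions) - 1) > 1e-9 || any(fractions <= 0))
    hs_validation_error("'fractions' must be positive and sum to 1")
  subjects <- unique(truth$subject_id)
  if (length(subjects) < 2)
    hs_validation_error("at least 2 subjects are required for a grouped split")
  n_train <- max(1L, min(length(subjects) - 1L,
                         round(fractions[["train"]] * length(subjects))))
  perm <- withr::with_seed(seed, sample(subjects))
  train_subjects <- sort(perm[seq_len(n_train)])
  val_subjects <- sort(setdiff(subjects, train_subjects))
  list(train_ids = which(truth$subject_id %in% train_subjects),
       val_ids = which(truth$subject_id %in% val_subjects),
       train_subjects = train_subjects, val_subjects = val_subjects)
}

#' Deterministic reference segmenter for phantom frames
#'
#' Intensity-and-morphology segmentation that exploits the phantom's
#' contrast design: bright bone echoes are thresholded into class 1 and the
#' hypoechoic femoral head into class 2, followed by minimum-area cleaning
#' and largest-component selection for the head. It is exact on noise-free
#' phantoms and tolerant of the default mild corruption
#' (speckle variance <= 0.05, blur <= 1.5 px); it is not a general
#' ultrasound segmenter. An undetectable head yields an empty class 2, not
#' an error, so the adequacy gate can observe the missing landmark.
#'
#' @param image phantom frame (numeric matrix in \[0, 1\]).
#' @param bright_thr intensity at or above which pixels are bone candidates.
#' @param dark_thr intensity at or below which pixels are head candidates.
#' @param min_area components smaller than this are discarded.
#' @return integer label matrix (0 background, 1 acetabulum, 2 head).
#' @export
reference_segment <- function(image, bright_thr = 0.60, dark_thr = 0.20,
                              min_area = 40) {
  if (!is.matrix(image)) hs_validation_error("'image' must be a matrix")
  H <- nrow(image); W <- ncol(image)
  mask <- matrix(0L, H, W)

  bone <- image >= bright_thr
  if (any(bone)) {
    lab <- EBImage::bwlabel(EBImage::Image(bone * 1))
    lab <- matrix(EBImage::imageData(lab), H, W)
    keep <- which(tabulate(lab[lab > 0], nbins = max(lab)) >= min_area)
    mask[lab %in% keep] <- 1L
  }

  dark <- image <= dark_thr
  if (any(dark)) {
    comp <- largest_component(dark)
    if (sum(comp) >= min_area) {
      comp <- matrix(EBImage::imageData(EBImage::fillHull(EBImage::Image(comp * 1))),
                     H, W) > 0
      mask[comp] <- 2L
    }
  }
  mask
}
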