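## Classed conditions so callers (and tests) can distinguish failure modes.
hs_stop <- function(msg, class, call = sys.call(-1)) {
  stop(structure(
    class = c(class, "hipscreen_error", "error", "condition"),
    list(message = msg, call = call)
  ))
}

hs_validation_error <- function(msg) hs_stop(msg, "hipscreen_validation_error")
hs_missing_landmark_error <- function(msg) hs_stop(msg, "hipscreen_missing_landmark_error")
hs_degenerate_error <- function(msg) hs_stop(msg, "hipscreen_degenerate_error")
hs_undefined_rate_error <- function(msg) hs_stop(msg, "hipscreen_undefined_rate_error")
hs_io_error <- function(msg) hs_stop(msg, "hipscreen_io_error")

check_scalar <- function(x, name, min = -Inf, max = Inf, integer = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    hs_validation_error(sprintf("'%s' must be a finite numeric scalar", name))
  if (integer && x != round(x))
    hs_validation_error(sprintf("'%s' must be an integer", name))
  if (x < min || x > max)
    hs_validation_error(sprintf("'%s' must be in [%s, %s], got %s", name, min, max, x))
  invisible(x)
}

#' Round half away from zero
#'
#' Deterministic decimal rounding used for all reported percentages, so that
#' printed summary values recompute exactly from integer counts (base
#' `round()` uses round-half-to-even, which would make e.g. 2.5 print as 2).
#'
#' @param x numeric vector.
#' @param digits number of decimal places.
#' @return rounded numeric vector.
#' @export
round_half_up <- function(x, digits = 0) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

## dimension-preserving clamp to [0, 1] (pmin/pmax would copy attributes
## from their scalar first argument and drop dims)
clip01 <- function(x) {
  x[x < 0] <- 0
  x[x > 1] <- 1
  x
}

## Cheap deterministic fingerprint of a numeric parameter set; used to stamp
## checkpoints and CLI artifacts without a hashing dependency.
param_checksum <- function(params) {
  vals <- unlist(params, use.names = FALSE)
  num <- suppressWarnings(as.numeric(vals))
  num <- num[is.finite(num)]
  chr <- if (is.character(vals)) sum(nchar(vals)) else 0L
  sprintf("%d:%d:%.10e:%.10e", length(vals), chr, sum(num), sum(abs(num)))
}

## EBImage wrappers: hipscreen matrices are (row, col) with origin top-left;
## EBImage's first dimension maps onto our rows, so dimensions pass through.
resize_bilinear <- function(mat, out_rows, out_cols) {
  if (nrow(mat) == out_rows && ncol(mat) == out_cols) return(mat)
  out <- EBImage::resize(EBImage::Image(mat), w = out_rows, h = out_cols,
                         filter = "bilinear")
  matrix(EBImage::imageData(out), out_rows, out_cols)
}

resize_nearest <- function(mat, out_rows, out_cols) {
  if (nrow(mat) == out_rows && ncol(mat) == out_cols) return(mat)
  out <- EBImage::resize(EBImage::Image(mat), w = out_rows, h = out_cols,
                         filter = "none")
  matrix(EBImage::imageData(out), out_rows, out_cols)
}

gaussian_blur <- function(mat, sigma) {
  if (sigma <= 0) return(mat)
  out <- EBImage::gblur(EBImage::Image(mat), sigma = sigma)
  matrix(EBImage::imageData(out), nrow(mat), ncol(mat))
}

largest_component <- function(binary) {
  lab <- EBImage::bwlabel(EBImage::Image(binary * 1))
  lab <- matrix(EBImage::imageData(lab), nrow(binary), ncol(binary))
  n <- max(lab)
  if (n < 1) return(matrix(FALSE, nrow(binary), ncol(binary)))
  if (n == 1) return(lab == 1)
  sizes <- tabulate(lab[lab > 0], nbins = n)
  lab == which.max(sizes)
}

#' Read and write label-mask PNG files
#'
#' Masks are stored as 8-bit grayscale PNGs whose raw byte values are the
#' labels themselves (0 = background, 1 = acetabulum-ilium complex,
#' 2 = femoral head).
#'
#' @param mask integer label matrix.
#' @param path file path.
#' @return `read_mask_png` returns an integer label matrix.
#' @export
write_mask_png <- function(mask, path) {
  png::writePNG(mask / 255, target = path)
  invisible(path)
}

#' @rdname write_mask_png
#' @export
read_mask_png <- function(path) {
  m <- png::readPNG(path)
  if (length(dim(m)) == 3L) m <- m[, , 1]
  matrix(as.integer(round(m * 255)), nrow(m), ncol(m))
}

#' Read and write grayscale image PNG files
#'
#' Images are stored as 8-bit grayscale PNG with intensities mapped from
#' \[0, 1\].
#'
#' @param image numeric matrix in \[0, 1\].
#' @param path file path.
#' @return `read_image_png` returns a numeric matrix in \[0, 1\].
#' @export
write_image_png <- function(image, path) {
  png::writePNG(clip01(image), target = path)
  invisible(path)
}

#' @rdname read_mask_png
#' @export
read_image_png <- function(path) {
  m <- png::readPNG(path)
  if (length(dim(m)) == 3L) m <- m[, , 1]
  matrix(m, nrow(m), ncol(m))
}
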