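# Radiograph preprocessing: unsharp-mask sharpening, global histogram
# equalization, and fixed 3x3 Gaussian smoothing, composed in that order.

# Binomial 3x3 Gaussian kernel (sigma ~ 0.85); weights sum to 1.
GAUSSIAN_3X3 <- matrix(c(1, 2, 1, 2, 4, 2, 1, 2, 1), 3L, 3L) / 16

# 3x3 convolution with edge-replication (half-sample reflect) padding.
# The padded operator is column-stochastic for a normalized kernel, so the
# global intensity sum is preserved exactly before rounding.
conv3x3 <- function(m, kernel) {
  nr <- nrow(m); nc <- ncol(m)
  pad <- rbind(m[1L, , drop = FALSE], m, m[nr, , drop = FALSE])
  pad <- cbind(pad[, 1L, drop = FALSE], pad, pad[, nc, drop = FALSE])
  out <- matrix(0, nr, nc)
  for (di in 0:2) {
    for (dj in 0:2) {
      out <- out + kernel[di + 1L, dj + 1L] *
        pad[di + seq_len(nr), dj + seq_len(nc)]
    }
  }
  out
}

clip8 <- function(m) {
  m <- round(pmin(pmax(m, 0), 255))
  storage.mode(m) <- "integer"
  m
}

#' Sharpen an image by unsharp masking
#'
#' `output = clip(input + amount * (input - blur(input)))`, with the fixed
#' 3x3 Gaussian as the blur. `amount = 0` is the identity; constant images
#' are unchanged for any amount.
#'
#' @param image Integer matrix in `[0, 255]`.
#' @param amount Non-negative sharpening strength (default 1).
#' @return An image matrix of the same dimensions.
#' @export
sharpen <- function(image, amount = 1) {
  stopifnot(is.matrix(image), amount >= 0)
  if (amount == 0) return(clip8(image))
  blurred <- conv3x3(image, GAUSSIAN_3X3)
  clip8(image + amount * (image - blurred))
}

#' Global histogram equalization
#'
#' Maps each gray level `k` to `round(255 * cdf(k))` where `cdf` is the
#' empirical cumulative distribution of intensities over the full frame.
#' The mapping is monotone non-decreasing; a single-level image stays
#' single-level.
#'
#' @inheritParams sharpen
#' @return An image matrix of the same dimensions.
#' @export
equalize_histogram <- function(image) {
  stopifnot(is.matrix(image))
  counts <- tabulate(as.integer(image) + 1L, nbins = 256L)
  cdf <- cumsum(counts) / length(image)
  lut <- as.integer(round(255 * cdf))
  out <- matrix(lut[as.integer(image) + 1L], nrow(image), ncol(image))
  out
}

#' Smooth an image with the fixed 3x3 Gaussian kernel
#'
#' Convolution with `(1/16) [1 2 1; 2 4 2; 1 2 1]` under edge-replication
#' padding, which preserves the global mean intensity up to rounding.
#'
#' @inheritParams sharpen
#' @return An image matrix of the same dimensions.
#' @export
gaussian_smooth <- function(image) {
  stopifnot(is.matrix(image))
  clip8(conv3x3(image, GAUSSIAN_3X3))
}

#' Run the enhancement chain
#'
#' Applies sharpening, histogram equalization and Gaussian smoothing, in
#' that order, per the configuration flags.
#'
#' @inheritParams sharpen
#' @param sharpen_amount Unsharp-mask strength; `NULL` or 0 disables the step.
#' @param equalize Apply global histogram equalization?
#' @param smooth Apply the 3x3 Gaussian smoothing step?
#' @return An image matrix of the same dimensions.
#' @export
enhance <- function(image, sharpen_amount = 1, equalize = TRUE, smooth = TRUE) {
  out <- clip8(image)
  if (!is.null(sharpen_amount) && sharpen_amount > 0) {
    out <- sharpen(out, sharpen_amount)
  }
  if (isTRUE(equalize)) out <- equalize_histogram(out)
  if (isTRUE(smooth)) out <- gaussian_smooth(out)
  out
}
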