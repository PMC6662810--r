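#' Gray-level co-occurrence matrix (GLCM)
#'
#' Counts pairs of gray levels separated by `distance` pixels along one of
#' the four canonical directions (0, 45, 90, 135 degrees), in both orders,
#' and normalizes the counts to sum to 1. With 0 degrees pointing right and
#' rows growing downward, 45 degrees points up-right. When the image carries
#' a mask, pairs with either pixel outside the mask are excluded.
#'
#' @param qimage a `quantized_image` from [quantize()].
#' @param distance positive integer pixel offset d.
#' @param direction one of `"0"`, `"45"`, `"90"`, `"135"` (numeric accepted).
#' @return object of class `glcm`: list with `counts` (G x G symmetric
#'   matrix summing to 1), `direction`, `distance`, `levels`, `npairs`.
#' @references Haralick RM, Shanmugam K, Dinstein I (1973) Textural
#'   features for image classification. IEEE Trans Syst Man Cybern 3:610-621.
#' @export
compute_glcm <- function(qimage, distance = 3L, direction = "0") {
  stopifnot(inherits(qimage, "quantized_image"))
  distance <- as.integer(distance)
  if (is.na(distance) || distance < 1L) stop("`distance` must be >= 1")
  px <- qimage$pixels
  nr <- nrow(px); nc <- ncol(px)
  if (nr <= distance || nc <= distance)
    stop("image dimensions must exceed the co-occurrence distance")
  off <- direction_offset(direction, distance)
  dr <- off[1L]; dc <- off[2L]
  r0 <- max(1L, 1L - dr):min(nr, nr - dr)
  c0 <- max(1L, 1L - dc):min(nc, nc - dc)
  a <- px[r0, c0, drop = FALSE]
  b <- px[r0 + dr, c0 + dc, drop = FALSE]
  keep <- TRUE
  if (!is.null(qimage$mask)) {
    keep <- qimage$mask[r0, c0, drop = FALSE] &
      qimage$mask[r0 + dr, c0 + dc, drop = FALSE]
    a <- a[keep]; b <- b[keep]
  }
  if (length(a) == 0L)
    stop("no valid pixel pairs for this distance/direction (degenerate input)")
  G <- qimage$levels
  cnt <- tabulate(a * G + b + 1L, nbins = G * G)
  cnt <- matrix(cnt, G, G, byrow = TRUE)     # row = first pixel's level
  cnt <- cnt + t(cnt)                         # count both orders: symmetric
  structure(list(counts = cnt / sum(cnt),
                 direction = as.character(sub("^deg", "", direction)),
                 distance = distance, levels = G, npairs = length(a)),
            class = "glcm")
}

#' Haralick texture parameters of a GLCM
#'
#' Computes the eleven co-occurrence parameters used throughout the
#' pipeline: angular second moment, contrast, correlation, variance
#' (sum of squares), sum of variance, mean sum (sum average), entropy,
#' sum entropy, entropy difference (difference entropy), residual variance
#' (difference variance) and inverse difference moment. Entropies use the
#' natural logarithm with the convention 0 log 0 = 0. Gray levels are
#' indexed 0..G-1.
#'
#' On a constant image the marginal variance is zero and correlation is
#' undefined; it is returned as `NA` with a warning, never silently zero.
#'
#' @param glcm a `glcm` object from [compute_glcm()].
#' @return named numeric vector of length 11 (names in
#'   [glcm_parameter_names()] order).
#' @export
glcm_features <- function(glcm) {
  stopifnot(inherits(glcm, "glcm"))
  p <- glcm$counts
  G <- glcm$levels
  stopifnot(abs(sum(p) - 1) < 1e-8)
  i <- matrix(0:(G - 1), G, G)          # row level
  j <- t(i)                             # col level
  lev <- 0:(G - 1)
  px_marg <- rowSums(p)                 # symmetric: equals colSums
  mu <- sum(lev * px_marg)
  sig2 <- sum((lev - mu)^2 * px_marg)

  # sum distribution p_{x+y}(k), k = 0..2(G-1), and difference p_{x-y}(k)
  psum <- vapply(0:(2 * G - 2), function(k) sum(p[i + j == k]), numeric(1))
  pdiff <- vapply(0:(G - 1), function(k) sum(p[abs(i - j) == k]), numeric(1))

  xlogx <- function(q) ifelse(q > 0, q * log(q), 0)
  sum_avg <- sum((0:(2 * G - 2)) * psum)
  diff_avg <- sum((0:(G - 1)) * pdiff)

  corr <- if (sig2 <= .Machine$double.eps) {
    warning("correlation undefined: zero marginal variance (constant image)")
    NA_real_
  } else (sum(i * j * p) - mu^2) / sig2

  c(
    angular_second_moment = sum(p^2),
    contrast = sum((i - j)^2 * p),
    correlation = corr,
    variance = sum((i - mu)^2 * p),
    sum_of_variance = sum(((0:(2 * G - 2)) - sum_avg)^2 * psum),
    mean_sum = sum_avg,
    entropy = -sum(xlogx(p)),
    sum_entropy = -sum(xlogx(psum)),
    entropy_difference = -sum(xlogx(pdiff)),
    residual_variance = sum(((0:(G - 1)) - diff_avg)^2 * pdiff),
    inverse_difference_moment = sum(p / (1 + (i - j)^2))
  )
}

#' Names of the texture parameters
#'
#' @return character vectors giving the fixed order of the 11 GLCM and 4
#'   GLRLM parameter names used in all feature tables.
#' @export
glcm_parameter_names <- function() {
  c("angular_second_moment", "contrast", "correlation", "variance",
    "sum_of_variance", "mean_sum", "entropy", "sum_entropy",
    "entropy_difference", "residual_variance", "inverse_difference_moment")
}

#' @rdname glcm_parameter_names
#' @export
glrlm_parameter_names <- function() {
  c("run_length_nonuniformity", "grey_level_nonuniformity",
    "short_run_emphasis", "long_run_emphasis")
}

#' @rdname glcm_parameter_names
#' @export
texture_parameter_names <- function() {
  c(glcm_parameter_names(), glrlm_parameter_names())
}
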