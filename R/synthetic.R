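# separable Gaussian smoothing with edge-replicated padding; kernel
# truncated at 3 sigma
.gauss_blur <- function(m, sigma_row, sigma_col = sigma_row) {
  pad_filter <- function(x, sigma) {    # filter every column, replicate edges
    r <- max(1L, ceiling(3 * sigma))
    k <- stats::dnorm(-r:r, sd = sigma)
    k <- k / sum(k)
    xp <- rbind(x[rep(1L, r), , drop = FALSE], x,
                x[rep(nrow(x), r), , drop = FALSE])
    f <- stats::filter(xp, k, method = "convolution", sides = 2L)
    matrix(f[(r + 1L):(r + nrow(x)), ], nrow(x), ncol(x))
  }
  t(pad_filter(t(pad_filter(m, sigma_row)), sigma_col))
}

# run code with a private RNG state so generators are pure functions of
# (params, seed) and never disturb the caller's random stream
.with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

#' Synthetic image class parameters
#'
#' Parameter sets controlling the two synthetic trabecular image classes.
#' Images are thresholded Gaussian random fields: `correlation_length`
#' sets the spatial scale of the structure (pixels), `fill_fraction` the
#' bone area fraction, `blur_sigma` the optical blur of the low-power
#' lens (pixels) and `noise_sd` the additive pixel noise (gray levels,
#' 0-255 scale).
#'
#' The sham-operated (SHAM) defaults produce finer, denser, more complex
#' structure than the ovariectomized (OVX) defaults, mirroring the loss
#' of trabecular bone and coarsening of the remaining network in
#' estrogen-deficient osteoporosis.
#'
#' @param correlation_length,fill_fraction,blur_sigma,noise_sd,image_size
#'   see description; `image_size` is the square image side in pixels.
#' @param anisotropy ratio of vertical to horizontal correlation length
#'   (> 1 elongates structure vertically, emulating the load-aligned
#'   orientation of trabeculae).
#' @param perforation fraction of the trabecular area carved out again by
#'   a fine-scale erosion field, producing ragged edges and holes; the
#'   initial threshold is compensated so the final mask still covers
#'   `fill_fraction`. Perforation of trabeculae is a hallmark of
#'   estrogen-deficient bone loss, so the OVX default is markedly higher.
#' @return named list of class parameters.
#' @export
image_class_params <- function(correlation_length = 7, fill_fraction = 0.42,
                               blur_sigma = 2.5, noise_sd = 25,
                               image_size = 512L, anisotropy = 1.5,
                               perforation = 0.05) {
  stopifnot(correlation_length >= 1, fill_fraction > 0, fill_fraction < 1,
            blur_sigma >= 0, noise_sd >= 0, image_size >= 32L,
            anisotropy > 0, perforation >= 0, perforation < 0.5)
  list(correlation_length = correlation_length,
       fill_fraction = fill_fraction, blur_sigma = blur_sigma,
       noise_sd = noise_sd, image_size = as.integer(image_size),
       anisotropy = anisotropy, perforation = perforation)
}

#' @rdname image_class_params
#' @export
sham_params <- function() image_class_params(correlation_length = 7,
                                             fill_fraction = 0.42,
                                             anisotropy = 1.5,
                                             perforation = 0.02)

#' @rdname image_class_params
#' @export
ovx_params <- function() image_class_params(correlation_length = 8.8,
                                            fill_fraction = 0.375,
                                            anisotropy = 1.28,
                                            perforation = 0.25)

#' Generate one synthetic trabecular image with its mask
#'
#' A seeded white-noise field is smoothed with a Gaussian kernel of scale
#' `correlation_length` and thresholded at the `1 - fill_fraction`
#' quantile, giving a trabecular-like binary mask covering
#' `fill_fraction` of the image. The mask is rendered with soft edges,
#' blurred with `blur_sigma` (emulating the low-power optics) and
#' corrupted with Gaussian pixel noise. Deterministic given
#' `(params, seed)`.
#'
#' @param params an [image_class_params()] list.
#' @param seed integer seed.
#' @return list with `image` (numeric matrix, gray values in \[0, 255\]),
#'   `mask` (logical matrix), `params`, `seed`.
#' @export
gen_trabecular_image <- function(params = sham_params(), seed = 1L) {
  .with_seed(seed, {
    n <- params$image_size
    field <- matrix(stats::rnorm(n * n), n, n)
    aniso <- if (is.null(params$anisotropy)) 1 else params$anisotropy
    perf <- if (is.null(params$perforation)) 0 else params$perforation
    smooth <- .gauss_blur(field,
                          sigma_row = params$correlation_length * sqrt(aniso),
                          sigma_col = params$correlation_length / sqrt(aniso))
    # carve `perforation` of the area out again below, so threshold more
    # generously here to land on fill_fraction coverage overall
    fill_eff <- min(0.95, params$fill_fraction / (1 - perf))
    thr <- stats::quantile(smooth, 1 - fill_eff)
    silhouette <- smooth > thr
    mask <- silhouette
    if (perf > 0 && any(mask)) {
      fine <- .gauss_blur(matrix(stats::rnorm(n * n), n, n), sigma_row = 1.5)
      mask <- mask & fine >= stats::quantile(fine[mask], perf)
    }
    if (!any(mask) || all(mask)) stop("parameters yield a degenerate mask")
    # the gray image is rendered from the smooth silhouette: resorption
    # cavities are visible to the delineator (the ROI mask) but below the
    # resolving power of the blurred low-power optics
    rendered <- .gauss_blur(ifelse(silhouette, 0.75, 0.15),
                            sigma_row = max(params$blur_sigma, 0.5))
    img <- rendered * 255 + stats::rnorm(n * n, sd = params$noise_sd)
    img <- matrix(pmin(pmax(img, 0), 255), n, n)
    list(image = img, mask = mask, params = params, seed = seed)
  })
}

#' Generate a labeled two-class synthetic image dataset
#'
#' Default sizes (34 SHAM, 18 OVX) mirror a typical small animal study.
#' Each image receives its own structural parameters, drawn around the
#' class means with between-animal variability
#' (`correlation_length_sd`, `fill_fraction_sd`): the class
#' distributions overlap, so single images are not trivially separable
#' while the class contrast (SHAM finer and denser than OVX) holds in
#' the mean. Per-image seeds are derived deterministically from the
#' master seed.
#'
#' @param n_sham,n_ovx class sizes (default 34 and 18).
#' @param sham_params,ovx_params class mean parameter lists.
#' @param correlation_length_sd,fill_fraction_sd,perforation_sd,anisotropy_sd
#'   between-animal standard deviations of the structural parameters;
#'   with the class-mean defaults these give overlapping class
#'   distributions (single animals are not trivially separable) while
#'   preserving the mean contrast.
#' @param seed master seed.
#' @return list with `images` (list of [gen_trabecular_image()] outputs)
#'   and `labels` (factor with levels `SHAM`, `OVX`).
#' @export
gen_dataset <- function(n_sham = 34L, n_ovx = 18L,
                        sham_params = trabtex::sham_params(),
                        ovx_params = trabtex::ovx_params(),
                        correlation_length_sd = 1.5,
                        fill_fraction_sd = 0.06,
                        perforation_sd = 0.04,
                        anisotropy_sd = 0.15, seed = 1L) {
  stopifnot(n_sham >= 1L, n_ovx >= 1L)
  n <- n_sham + n_ovx
  labels <- factor(rep(c("SHAM", "OVX"), c(n_sham, n_ovx)),
                   levels = c("SHAM", "OVX"))
  draws <- .with_seed(seed, list(
    cl = stats::rnorm(n, sd = correlation_length_sd),
    ff = stats::rnorm(n, sd = fill_fraction_sd),
    pf = stats::rnorm(n, sd = perforation_sd),
    an = stats::rnorm(n, sd = anisotropy_sd),
    seeds = sample.int(2147483646L, n)
  ))
  images <- lapply(seq_len(n), function(i) {
    p <- if (labels[i] == "SHAM") sham_params else ovx_params
    p$correlation_length <- max(1, p$correlation_length + draws$cl[i])
    p$fill_fraction <- min(0.9, max(0.05, p$fill_fraction + draws$ff[i]))
    p$perforation <- min(0.45, max(0, p$perforation + draws$pf[i]))
    p$anisotropy <- max(0.7, p$anisotropy + draws$an[i])
    gen_trabecular_image(p, seed = draws$seeds[i])
  })
  list(images = images, labels = labels)
}

#' Generate a labeled feature matrix with known ground truth
#'
#' Stand-in for a real 28-column feature table with a known informative
#' support: informative columns are Normal(+delta/2, 1) in class +1 and
#' Normal(-delta/2, 1) in class -1; redundant columns copy a randomly
#' chosen informative column plus Normal(0, `redundancy_noise_sd`) noise
#' (emulating the strong inter-feature correlations of real texture
#' tables); noise columns are Normal(0, 1) independent of the label.
#'
#' @param n1,n2 class sizes (class +1 first).
#' @param p_informative,p_redundant,p_noise column counts.
#' @param effect_size class mean separation delta of informative columns.
#' @param redundancy_noise_sd noise added to redundant copies.
#' @param seed integer seed.
#' @return list with `A` (n x p matrix, columns named and ordered
#'   informative, redundant, noise), `y` (-1/+1), `true_support`
#'   (informative column indices), `redundant` and `noise` index vectors.
#' @export
gen_feature_matrix <- function(n1 = 30L, n2 = 30L, p_informative = 8L,
                               p_redundant = 0L, p_noise = 20L,
                               effect_size = 2, redundancy_noise_sd = 0.3,
                               seed = 1L) {
  stopifnot(p_informative >= 1L, p_redundant >= 0L, p_noise >= 0L,
            effect_size >= 0, n1 >= 1L, n2 >= 1L)
  .with_seed(seed, {
    n <- n1 + n2
    y <- c(rep(1, n1), rep(-1, n2))
    mu <- y * effect_size / 2
    inf <- matrix(stats::rnorm(n * p_informative, mean = mu),
                  n, p_informative)
    red <- if (p_redundant > 0L) {
      src <- sample.int(p_informative, p_redundant, replace = TRUE)
      inf[, src, drop = FALSE] +
        matrix(stats::rnorm(n * p_redundant, sd = redundancy_noise_sd),
               n, p_redundant)
    } else matrix(numeric(0), n, 0L)
    noi <- matrix(stats::rnorm(n * p_noise), n, p_noise)
    A <- cbind(inf, red, noi)
    colnames(A) <- c(sprintf("inf%02d", seq_len(p_informative)),
                     if (p_redundant > 0L) sprintf("red%02d",
                                                   seq_len(p_redundant)),
                     if (p_noise > 0L) sprintf("noise%02d",
                                               seq_len(p_noise)))
    list(A = A, y = y, true_support = seq_len(p_informative),
         redundant = if (p_redundant > 0L)
           p_informative + seq_len(p_redundant) else integer(0),
         noise = if (p_noise > 0L)
           p_informative + p_redundant + seq_len(p_noise) else integer(0))
  })
}
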