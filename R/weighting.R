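#' Per-direction texture parameter table for one image
#'
#' Computes all 15 texture parameters (11 GLCM at the given distance,
#' 4 GLRLM) in each of the four canonical directions.
#'
#' @inheritParams compute_glcm
#' @return a 15 x 4 numeric matrix (class `directional_table`); rows are
#'   [texture_parameter_names()], columns the directions
#'   `c("0","45","90","135")`; attribute `distance` records the GLCM
#'   distance used.
#' @export
directional_table <- function(qimage, distance = 3L) {
  dirs <- texture_directions()
  tab <- matrix(NA_real_, 15L, 4L,
                dimnames = list(texture_parameter_names(), dirs))
  for (d in dirs) {
    tab[glcm_parameter_names(), d] <-
      glcm_features(compute_glcm(qimage, distance = distance, direction = d))
    tab[glrlm_parameter_names(), d] <-
      glrlm_features(compute_glrlm(qimage, direction = d))
  }
  structure(tab, distance = as.integer(distance), class = "directional_table")
}

#' @describeIn directional_table long-form view: one row per direction,
#'   with `direction` and `distance` columns followed by the 15
#'   parameter columns.
#' @param x a `directional_table`.
#' @param ... ignored.
#' @export
as.data.frame.directional_table <- function(x, ...) {
  data.frame(direction = colnames(x), distance = attr(x, "distance"),
             t(unclass(x)), check.names = FALSE, row.names = NULL)
}

#' Direction-weighting primitives (variation coefficient method)
#'
#' For one sample, the four values `x` of the most direction-sensitive
#' parameter determine a weight per direction: the mean
#' `m = mean(x)`, per-direction variation coefficients
#' `v_j = |x_j - m| / m`, and weights `w_j = v_j / sum(v)`. The weighted
#' final value of any parameter `p` measured in the four directions is
#' `sum(w * p)`. Directions where the sentinel deviates more from its mean
#' thus contribute more, emphasising the anisotropy the sentinel detects.
#'
#' Degenerate inputs (`m == 0`, or an isotropic sentinel with all
#' `v_j == 0`) fall back to uniform weights 1/4, which reduces the
#' weighted value to the plain directional average.
#'
#' @param x numeric(4): sentinel parameter values in directions
#'   0, 45, 90, 135.
#' @return `direction_mean`: scalar mean; `variation_coefficients`:
#'   numeric(4) of nonnegative coefficients; `direction_weights`:
#'   numeric(4) summing to 1; `weighted_value`: scalar convex combination.
#' @name direction_weighting
NULL

#' @rdname direction_weighting
#' @export
direction_mean <- function(x) {
  stopifnot(length(x) == 4L, all(is.finite(x)))
  mean(x)
}

#' @rdname direction_weighting
#' @export
variation_coefficients <- function(x) {
  m <- direction_mean(x)
  if (m == 0) stop("degenerate sentinel: mean across directions is zero")
  abs(x - m) / m
}

#' @rdname direction_weighting
#' @param v numeric(4) of nonnegative variation coefficients.
#' @export
direction_weights <- function(v) {
  stopifnot(length(v) == 4L, all(v >= 0))
  s <- sum(v)
  if (s == 0) rep(0.25, 4L) else v / s
}

#' @rdname direction_weighting
#' @param w numeric(4) of weights summing to 1.
#' @param p numeric(4): any parameter's values in the four directions.
#' @export
weighted_value <- function(w, p) {
  stopifnot(length(w) == 4L, length(p) == 4L,
            abs(sum(w) - 1) < 1e-8, all(w >= 0))
  sum(w * p)
}

# weights from a sentinel row, with uniform fallback on any degeneracy
# (undefined sentinel, zero mean, or isotropic values with no variation)
.sentinel_weights <- function(x, what) {
  if (anyNA(x) || !all(is.finite(x)) || mean(x) == 0) {
    warning(sprintf("%s sentinel undefined; falling back to uniform weights",
                    what))
    return(rep(0.25, 4L))
  }
  v <- abs(x - mean(x)) / mean(x)
  if (sum(v) == 0) {
    warning(sprintf("%s sentinel is isotropic; falling back to uniform weights",
                    what))
    return(rep(0.25, 4L))
  }
  direction_weights(v)
}

#' Collapse a directional table to one value per parameter
#'
#' `weigh_table()` applies variation-coefficient weighting family-wise:
#' the GLCM sentinel (default `correlation`, the most direction-sensitive
#' co-occurrence parameter) yields the weight vector applied to all 11
#' GLCM parameters, and the GLRLM sentinel (default `long_run_emphasis`)
#' the one applied to all 4 run-length parameters. `simple_average_table()`
#' ignores sensitivity and takes the plain mean of the four directions.
#'
#' @param table a `directional_table` (single sample) or a list of them.
#' @param sentinel_glcm,sentinel_glrlm sentinel parameter names.
#' @return named numeric(15) for a single table; for a list, a matrix
#'   with one row per sample and 15 columns.
#' @export
weigh_table <- function(table, sentinel_glcm = "correlation",
                        sentinel_glrlm = "long_run_emphasis") {
  if (is.list(table) && !inherits(table, "directional_table"))
    return(t(vapply(table, weigh_table, numeric(15L),
                    sentinel_glcm = sentinel_glcm,
                    sentinel_glrlm = sentinel_glrlm)))
  stopifnot(all(c(sentinel_glcm, sentinel_glrlm) %in% rownames(table)))
  w_glcm <- .sentinel_weights(table[sentinel_glcm, ], "GLCM")
  w_glrlm <- .sentinel_weights(table[sentinel_glrlm, ], "GLRLM")
  out <- numeric(15L)
  names(out) <- texture_parameter_names()
  for (nm in glcm_parameter_names())
    out[nm] <- sum(w_glcm * table[nm, ])
  for (nm in glrlm_parameter_names())
    out[nm] <- sum(w_glrlm * table[nm, ])
  out
}

#' @rdname weigh_table
#' @export
simple_average_table <- function(table) {
  if (is.list(table) && !inherits(table, "directional_table"))
    return(t(vapply(table, simple_average_table, numeric(15L))))
  out <- rowMeans(unclass(table)[texture_parameter_names(), , drop = FALSE])
  out
}

#' Rank texture parameters by direction sensitivity
#'
#' Scores each parameter by the coefficient of variation across the four
#' directions (sd / |mean|), averaged over samples, and ranks parameters
#' within each family (GLCM, GLRLM) in decreasing order. The top-ranked
#' parameter of each family is the natural weighting sentinel.
#'
#' @param tables a list of `directional_table` objects (one per sample).
#' @return data.frame with columns `parameter`, `family`, `score`, sorted
#'   by family then decreasing score. Parameters whose directional mean is
#'   zero in some sample are excluded with a warning.
#' @export
rank_direction_sensitivity <- function(tables) {
  if (inherits(tables, "directional_table")) tables <- list(tables)
  stopifnot(length(tables) >= 1L)
  params <- texture_parameter_names()
  scores <- vapply(params, function(nm) {
    per_sample <- vapply(tables, function(tb) {
      x <- tb[nm, ]
      m <- mean(x)
      if (!all(is.finite(x)) || m == 0) return(NA_real_)
      stats::sd(x) / abs(m)
    }, numeric(1))
    mean(per_sample)
  }, numeric(1))
  if (anyNA(scores)) {
    warning("excluded from sensitivity ranking (zero or undefined mean): ",
            paste(params[is.na(scores)], collapse = ", "))
  }
  fam <- ifelse(params %in% glcm_parameter_names(), "GLCM", "GLRLM")
  out <- data.frame(parameter = params, family = fam, score = scores,
                    row.names = NULL)
  out <- out[!is.na(out$score), ]
  out[order(out$family, -out$score), ]
}

#' Recommend a stable co-occurrence distance from a mean-value profile
#'
#' Given mean parameter values on an ascending grid of distances, the
#' recommended distance is the smallest d whose relative change to the
#' next distance, `|x(d+1) - x(d)| / |x(d)|`, is below `threshold` for
#' every monitored parameter. If no distance qualifies, the distance with
#' the smallest total relative change to its successor is returned with a
#' warning.
#'
#' @param profile numeric matrix (distances x parameters) of mean values;
#'   rownames are the distances. A vector is treated as one parameter.
#' @param distances ascending integer distances (defaults to rownames).
#' @param threshold maximum relative change still considered stable
#'   (default 0.05, i.e. 5 percent).
#' @return list with `recommended` (integer distance), `stable` (logical),
#'   and `relative_change` (matrix of step-wise relative changes).
#' @export
recommend_distance <- function(profile, distances = NULL, threshold = 0.05) {
  if (is.vector(profile)) profile <- matrix(profile, ncol = 1L)
  if (is.null(distances)) {
    distances <- if (!is.null(rownames(profile)))
      as.integer(rownames(profile)) else seq_len(nrow(profile))
  }
  if (nrow(profile) < 2L) stop("need at least 2 distances")
  stopifnot(length(distances) == nrow(profile), !is.unsorted(distances))
  nd <- nrow(profile)
  rel <- abs(profile[-1L, , drop = FALSE] - profile[-nd, , drop = FALSE]) /
    abs(profile[-nd, , drop = FALSE])
  rownames(rel) <- distances[-nd]
  ok <- apply(rel < threshold, 1L, all)
  if (any(ok)) {
    list(recommended = distances[which(ok)[1L]], stable = TRUE,
         relative_change = rel)
  } else {
    warning("no distance reached stability below the threshold; ",
            "returning the distance with minimal total change")
    tot <- rowSums(rel)
    cand <- which(tot == min(tot))
    list(recommended = distances[cand[length(cand)]], stable = FALSE,
         relative_change = rel)
  }
}

#' Distance-stability analysis of GLCM parameters
#'
#' Computes the monitored GLCM parameters at each candidate distance
#' (averaged over the four directions and over images) and recommends the
#' smallest distance at which all monitored parameters have stabilised
#' (see [recommend_distance()]).
#'
#' @param qimages a `quantized_image` or list of them.
#' @param distances ascending integer vector of candidate distances
#'   (default 1:5).
#' @param parameters monitored GLCM parameter names (default the four
#'   classical indicators: contrast, correlation, entropy, inverse
#'   difference moment).
#' @inheritParams recommend_distance
#' @return list with `profile` (distances x parameters matrix of means),
#'   `recommended`, `stable`, `relative_change`.
#' @export
distance_stability <- function(qimages, distances = 1:5,
                               parameters = c("contrast", "correlation",
                                              "entropy",
                                              "inverse_difference_moment"),
                               threshold = 0.05) {
  if (inherits(qimages, "quantized_image")) qimages <- list(qimages)
  if (length(distances) < 2L) stop("need at least 2 distances")
  if (is.unsorted(distances)) stop("`distances` must be ascending")
  stopifnot(all(parameters %in% glcm_parameter_names()))
  prof <- matrix(NA_real_, length(distances), length(parameters),
                 dimnames = list(distances, parameters))
  for (k in seq_along(distances)) {
    per_img <- vapply(qimages, function(q) {
      vals <- vapply(texture_directions(), function(d) {
        glcm_features(compute_glcm(q, distance = distances[k],
                                   direction = d))[parameters]
      }, numeric(length(parameters)))
      rowMeans(matrix(vals, nrow = length(parameters)))
    }, numeric(length(parameters)))
    prof[k, ] <- rowMeans(matrix(per_img, nrow = length(parameters)))
  }
  rec <- recommend_distance(prof, distances = distances, threshold = threshold)
  c(list(profile = prof), rec)
}
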