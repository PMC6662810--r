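#' Pipeline configuration
#'
#' Central configuration with documented defaults; unknown keys are
#' rejected. Defaults: 64 gray levels, GLCM distance 3 (the distance at
#' which the co-occurrence parameters stabilise at low magnification),
#' correlation / long run emphasis as the direction-weighting sentinels,
#' area-weighted shape aggregation, ISTA tolerance 1e-6, SVM cost 1.
#'
#' @param ... named overrides of the defaults listed below.
#' @return named list of class `pipeline_config`.
#' @export
pipeline_config <- function(...) {
  defaults <- list(
    levels = 64L,
    glcm_distance = 3L,
    stability_distances = 1:5,
    sentinel_glcm = "correlation",
    sentinel_glrlm = "long_run_emphasis",
    shape_min_area = 20L,
    shape_weighting = "area",
    lambda1 = NULL,
    lambda_grid = 30L,
    solver_tol = 1e-6,
    solver_max_iter = 10000L,
    svm_cost = 1,
    selection_scope = "full",
    seed = 1L
  )
  over <- list(...)
  if (length(over) > 0L) {
    if (is.null(names(over)) || any(names(over) == ""))
      stop("all configuration overrides must be named")
    bad <- setdiff(names(over), names(defaults))
    if (length(bad) > 0L)
      stop("unknown configuration key(s): ", paste(bad, collapse = ", "))
    defaults[names(over)] <- over
  }
  structure(defaults, class = "pipeline_config")
}

#' Load a pipeline configuration from a YAML file
#'
#' @param path YAML file whose top-level keys are [pipeline_config()]
#'   keys.
#' @return a `pipeline_config`.
#' @export
load_config <- function(path) {
  if (!requireNamespace("yaml", quietly = TRUE))
    stop("the `yaml` package is required to read configuration files")
  do.call(pipeline_config, yaml::read_yaml(path))
}

#' Extract the full 28-feature vector of one image
#'
#' Quantizes the image, computes the 15 texture parameters per direction,
#' collapses them by variation-coefficient weighting (and plain
#' averaging, kept for the unweighted pipeline variants), and computes
#' the 13 shape parameters from the mask.
#'
#' @param image numeric matrix of gray values in \[0, 255\].
#' @param mask binary matrix of trabecular foreground (required for the
#'   shape block).
#' @param config a [pipeline_config()].
#' @return list with `texture_weighted` (named numeric 15),
#'   `texture_simple` (named numeric 15), `shape` (named numeric 13),
#'   `features` (named numeric 28: weighted texture then shape) and the
#'   `directional` table.
#' @export
extract_image_features <- function(image, mask, config = pipeline_config()) {
  q <- quantize(image, levels = config$levels)
  dtab <- directional_table(q, distance = config$glcm_distance)
  tw <- weigh_table(dtab, sentinel_glcm = config$sentinel_glcm,
                    sentinel_glrlm = config$sentinel_glrlm)
  ts <- simple_average_table(dtab)
  sh <- aggregate_shape(mask, min_area = config$shape_min_area,
                        weighting = config$shape_weighting)
  list(texture_weighted = tw, texture_simple = ts, shape = sh,
       features = c(tw, sh), directional = dtab)
}

#' Extract feature matrices for a whole labeled dataset
#'
#' @param dataset a list with `images` (each a list holding `image` and
#'   `mask`, as produced by [gen_dataset()]) and `labels`.
#' @param config a [pipeline_config()].
#' @param verbose print progress.
#' @return list of class `dataset_features` with matrices
#'   `texture_weighted`, `texture_simple`, `shape` (one row per image)
#'   and the `labels` factor; ready for [run_variant()].
#' @export
extract_dataset_features <- function(dataset, config = pipeline_config(),
                                     verbose = FALSE) {
  n <- length(dataset$images)
  stopifnot(n >= 1L, length(dataset$labels) == n)
  tw <- matrix(NA_real_, n, 15L,
               dimnames = list(NULL, texture_parameter_names()))
  ts <- tw
  sh <- matrix(NA_real_, n, 13L,
               dimnames = list(NULL, shape_parameter_names()))
  for (i in seq_len(n)) {
    if (verbose) message(sprintf("extracting image %d/%d", i, n))
    f <- extract_image_features(dataset$images[[i]]$image,
                                dataset$images[[i]]$mask, config)
    tw[i, ] <- f$texture_weighted
    ts[i, ] <- f$texture_simple
    sh[i, ] <- f$shape
  }
  structure(list(texture_weighted = tw, texture_simple = ts, shape = sh,
                 labels = factor(dataset$labels)),
            class = "dataset_features")
}

#' Fixed column order of the fused 28-feature table
#' @return character(28): the 15 texture names then the 13 shape names.
#' @export
feature_column_names <- function() {
  c(texture_parameter_names(), shape_parameter_names())
}

#' Write / read the fused feature table as CSV
#'
#' One row per image: an `id` column, a `label` column, then the 28
#' feature columns in [feature_column_names()] order (weighted texture
#' then shape).
#'
#' @param features a `dataset_features` list.
#' @param path output CSV path.
#' @param ids optional image identifiers (default `img001`...).
#' @return `write_features_csv` invisibly returns the data.frame written;
#'   `read_features_csv` returns a list with the feature matrix `X`,
#'   `labels` and `ids`.
#' @export
write_features_csv <- function(features, path, ids = NULL) {
  X <- cbind(features$texture_weighted, features$shape)
  if (is.null(ids)) ids <- sprintf("img%03d", seq_len(nrow(X)))
  df <- data.frame(id = ids, label = as.character(features$labels),
                   X, check.names = FALSE)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(df)
}

#' @rdname write_features_csv
#' @export
read_features_csv <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE)
  need <- feature_column_names()
  missing_cols <- setdiff(need, colnames(df))
  if (length(missing_cols) > 0L)
    stop("feature CSV is missing column(s): ",
         paste(missing_cols, collapse = ", "))
  list(X = as.matrix(df[, need, drop = FALSE]),
       labels = factor(df$label), ids = df$id)
}
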