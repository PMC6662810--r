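#' Leave-one-out cross-validated linear SVM
#'
#' For each sample, a linear support vector machine (cost `cost`) is
#' trained on the remaining n - 1 samples — with feature standardization
#' statistics computed from the training fold only, so no information
#' leaks from the held-out sample — and the held-out sample is predicted.
#' Pooled confusion counts over all folds give the report.
#'
#' @param features numeric matrix or data.frame (samples x features).
#' @param labels two-level factor or character vector of class labels.
#' @param cost SVM regularization parameter C (default 1).
#' @param positive label of the positive class; by default `"OVX"` when
#'   present (the diseased state, so sensitivity is the osteoporosis
#'   detection rate), otherwise the second factor level.
#' @return object of class `classification_report`: list with `TP`, `TN`,
#'   `FP`, `FN`, `ACC`, `SEN`, `SPE`, `YI`, `n`, `positive`, and the
#'   per-sample `predictions`.
#' @export
loocv_svm <- function(features, labels, cost = 1, positive = NULL) {
  X <- as.matrix(features)
  storage.mode(X) <- "double"
  labels <- factor(labels)
  n <- nrow(X)
  if (n < 4L) stop("need at least 4 samples")
  if (nlevels(labels) != 2L) stop("`labels` must have exactly two classes")
  if (is.null(positive))
    positive <- if ("OVX" %in% levels(labels)) "OVX" else levels(labels)[2L]
  if (!positive %in% levels(labels)) stop("`positive` is not a label level")
  pred <- factor(rep(NA_character_, n), levels = levels(labels))
  for (i in seq_len(n)) {
    tr_x <- X[-i, , drop = FALSE]
    tr_y <- labels[-i]
    if (nlevels(droplevels(tr_y)) != 2L)
      stop("a training fold is missing a class")
    mu <- colMeans(tr_x)
    sd_ <- apply(tr_x, 2L, stats::sd)
    sd_[sd_ < 1e-12] <- 1               # constant-in-fold columns: center only
    tr_s <- sweep(sweep(tr_x, 2L, mu), 2L, sd_, "/")
    te_s <- (X[i, ] - mu) / sd_
    fit <- e1071::svm(tr_s, tr_y, kernel = "linear", cost = cost,
                      scale = FALSE)
    pred[i] <- stats::predict(fit, matrix(te_s, nrow = 1L))
  }
  pos <- labels == positive
  ppos <- pred == positive
  report <- metrics(TP = sum(pos & ppos), TN = sum(!pos & !ppos),
                    FP = sum(!pos & ppos), FN = sum(pos & !ppos))
  report$positive <- positive
  report$predictions <- pred
  report
}

#' Classification metrics from confusion counts
#'
#' `ACC = (TP + TN) / n`, `SEN = TP / (TP + FN)`,
#' `SPE = TN / (TN + FP)`, and the Youden index `YI = SEN + SPE - 1`.
#'
#' @param TP,TN,FP,FN nonnegative confusion counts.
#' @return a `classification_report` (without predictions).
#' @export
metrics <- function(TP, TN, FP, FN) {
  stopifnot(TP >= 0, TN >= 0, FP >= 0, FN >= 0)
  if (TP + FN == 0) stop("no positive samples: sensitivity undefined")
  if (TN + FP == 0) stop("no negative samples: specificity undefined")
  n <- TP + TN + FP + FN
  sen <- TP / (TP + FN)
  spe <- TN / (TN + FP)
  structure(list(TP = TP, TN = TN, FP = FP, FN = FN, n = n,
                 ACC = (TP + TN) / n, SEN = sen, SPE = spe,
                 YI = youden(sen, spe)),
            class = "classification_report")
}

#' Youden index
#'
#' `YI = SEN + SPE - 1`; values above 0.7 are conventionally taken as
#' clinically usable discrimination.
#'
#' @param sen,spe sensitivity and specificity in \[0, 1\].
#' @return scalar in \[-1, 1\].
#' @export
youden <- function(sen, spe) {
  stopifnot(sen >= 0, sen <= 1, spe >= 0, spe <= 1)
  sen + spe - 1
}

#' @export
print.classification_report <- function(x, ...) {
  cat(sprintf(
    "classification_report (n=%d, positive=%s)\n  TP=%d TN=%d FP=%d FN=%d\n  ACC=%.4f SEN=%.4f SPE=%.4f YI=%.4f\n",
    x$n, if (is.null(x$positive)) "?" else x$positive,
    x$TP, x$TN, x$FP, x$FN, x$ACC, x$SEN, x$SPE, x$YI))
  invisible(x)
}

.VARIANTS <- c("TNS", "TSNS", "TYS", "TSYS", "TSYLS", "TSYLC")

#' Run one pipeline variant on an extracted feature set
#'
#' The six variants differ in texture averaging, shape fusion and feature
#' selection:
#' \describe{
#'   \item{TNS}{simple-averaged texture only}
#'   \item{TSNS}{simple-averaged texture + shape}
#'   \item{TYS}{direction-weighted texture only}
#'   \item{TSYS}{direction-weighted texture + shape}
#'   \item{TSYLS}{Lasso-selected TSYS features}
#'   \item{TSYLC}{dispersion-model-selected TSYS features}
#' }
#' All variants are evaluated with [loocv_svm()]. For the two selection
#' variants the default (`selection_scope = "full"`) selects once on the
#' full dataset before cross-validation; `"nested"` repeats the selection
#' inside every training fold, the statistically safer mode.
#'
#' @param features a dataset feature set from
#'   [extract_dataset_features()]: list with matrices `texture_weighted`
#'   (n x 15), `texture_simple` (n x 15), `shape` (n x 13) and `labels`.
#' @param variant one of `"TNS"`, `"TSNS"`, `"TYS"`, `"TSYS"`, `"TSYLS"`,
#'   `"TSYLC"` (case-insensitive).
#' @param lambda1 L1 penalty for the selection variants; `NULL` (default)
#'   uses [choose_lambda()].
#' @param cost linear SVM cost (default 1).
#' @param selection_scope `"full"` or `"nested"`.
#' @return a `classification_report`, with elements `variant`,
#'   `selected` (data.frame of selected features, selection variants
#'   only) and `lambda1` added.
#' @export
run_variant <- function(features, variant, lambda1 = NULL, cost = 1,
                        selection_scope = c("full", "nested")) {
  variant <- toupper(variant)
  selection_scope <- match.arg(selection_scope)
  if (!variant %in% .VARIANTS)
    stop("unknown variant tag: ", variant)
  labels <- features$labels
  X <- switch(variant,
    TNS = features$texture_simple,
    TSNS = cbind(features$texture_simple, features$shape),
    TYS = features$texture_weighted,
    TSYS = ,
    TSYLS = ,
    TSYLC = cbind(features$texture_weighted, features$shape))
  selected <- NULL
  lam <- lambda1
  if (variant %in% c("TSYLS", "TSYLC")) {
    use_disp <- variant == "TSYLC"
    if (selection_scope == "nested")
      return(.run_nested(X, labels, use_disp, lambda1, cost, variant))
    prob <- selection_problem(X, labels)
    if (is.null(lam))
      lam <- choose_lambda(prob, svm_cost = cost,
                           use_dispersion = use_disp)$lambda1
    fit <- ista_solve(prob, lambda1 = lam, use_dispersion = use_disp)
    selected <- select_features(fit)
    if (nrow(selected) == 0L)
      stop("selection produced an empty support; lower lambda1")
    X <- X[, selected$feature, drop = FALSE]
  }
  rep_ <- loocv_svm(X, labels, cost = cost)
  rep_$variant <- variant
  rep_$selected <- selected
  rep_$lambda1 <- lam
  rep_
}

# nested selection: redo the feature selection inside every LOOCV fold
.run_nested <- function(X, labels, use_disp, lambda1, cost, variant) {
  labels <- factor(labels)
  n <- nrow(X)
  positive <- if ("OVX" %in% levels(labels)) "OVX" else levels(labels)[2L]
  pred <- factor(rep(NA_character_, n), levels = levels(labels))
  for (i in seq_len(n)) {
    prob <- selection_problem(X[-i, , drop = FALSE], labels[-i])
    lam <- lambda1
    if (is.null(lam))
      lam <- choose_lambda(prob, svm_cost = cost,
                           use_dispersion = use_disp)$lambda1
    fit <- ista_solve(prob, lambda1 = lam, use_dispersion = use_disp)
    sel <- select_features(fit)
    if (nrow(sel) == 0L) sel <- data.frame(feature = colnames(X)[1L])
    sub <- sel$feature
    tr_x <- X[-i, sub, drop = FALSE]
    mu <- colMeans(tr_x)
    sd_ <- apply(tr_x, 2L, stats::sd); sd_[sd_ < 1e-12] <- 1
    tr_s <- sweep(sweep(tr_x, 2L, mu), 2L, sd_, "/")
    te_s <- (X[i, sub] - mu) / sd_
    fit_svm <- e1071::svm(tr_s, labels[-i], kernel = "linear", cost = cost,
                          scale = FALSE)
    pred[i] <- stats::predict(fit_svm, matrix(te_s, nrow = 1L))
  }
  pos <- labels == positive
  ppos <- pred == positive
  out <- metrics(sum(pos & ppos), sum(!pos & !ppos),
                 sum(!pos & ppos), sum(pos & !ppos))
  out$positive <- positive
  out$predictions <- pred
  out$variant <- variant
  out$lambda1 <- lambda1
  out
}

#' Run all six pipeline variants
#'
#' @inheritParams run_variant
#' @return named list of six `classification_report`s
#'   (`TNS` ... `TSYLC`).
#' @export
run_all_variants <- function(features, lambda1 = NULL, cost = 1,
                             selection_scope = "full") {
  out <- lapply(.VARIANTS, function(v)
    run_variant(features, v, lambda1 = lambda1, cost = cost,
                selection_scope = selection_scope))
  names(out) <- .VARIANTS
  out
}
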