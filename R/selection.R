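#' Build a two-class feature-selection problem
#'
#' Assembles the standardized design matrix, class coding and intra-class
#' dispersion terms for the dispersion-penalized sparse selection model
#'
#' \deqn{\min_b \|Ab - Y\|_2^2 + \|C_1 \circ b\|_F^2 / n_1 +
#'       \|C_2 \circ b\|_F^2 / n_2 + \lambda_1 \|b\|_1}
#'
#' where \eqn{C_k} is class k's column-centered block and
#' \eqn{C \circ b} scales column j of C by \eqn{b_j}. The quadratic
#' dispersion terms shrink coefficients of features that scatter widely
#' within a class, on top of the ordinary Lasso fit-plus-sparsity
#' trade-off.
#'
#' @param A numeric matrix (samples x features).
#' @param y labels: numeric in \{-1, +1\} or a two-level factor (first
#'   level is coded +1).
#' @param lambda1 nonnegative L1 penalty; `NULL` to defer to
#'   [choose_lambda()].
#' @param standardize center and scale columns to unit variance (default
#'   TRUE; constant columns are dropped with a warning).
#' @return object of class `selection_problem`: list with `A`, `y`,
#'   `n1`, `n2`, `D1`, `D2` (dispersion diagonals), `S` (total intra-class
#'   dispersion), `feature_names`, `lambda1`.
#' @export
selection_problem <- function(A, y, lambda1 = NULL, standardize = TRUE) {
  A <- as.matrix(A)
  if (is.factor(y) || is.character(y)) {
    y <- factor(y)
    if (nlevels(y) != 2L) stop("`y` must have exactly two classes")
    y <- ifelse(y == levels(y)[1L], 1, -1)
  }
  y <- as.numeric(y)
  if (!all(y %in% c(-1, 1))) stop("`y` must be coded -1/+1 or two-level")
  if (nrow(A) != length(y)) stop("nrow(A) must equal length(y)")
  n1 <- sum(y == 1); n2 <- sum(y == -1)
  if (n1 < 1L || n2 < 1L) stop("both classes must be nonempty")
  nms <- colnames(A)
  if (is.null(nms)) nms <- paste0("f", seq_len(ncol(A)))
  if (standardize) {
    mu <- colMeans(A)
    sd_ <- apply(A, 2L, stats::sd)
    const <- sd_ < 1e-12
    if (any(const)) {
      warning("dropping constant feature column(s): ",
              paste(nms[const], collapse = ", "))
      A <- A[, !const, drop = FALSE]
      mu <- mu[!const]; sd_ <- sd_[!const]; nms <- nms[!const]
    }
    A <- sweep(sweep(A, 2L, mu), 2L, sd_, "/")
  }
  cc <- center_classes(A, y)
  disp <- intra_class_dispersion(cc$C1, cc$C2)
  structure(list(A = A, y = y, n1 = n1, n2 = n2,
                 D1 = disp$D1, D2 = disp$D2, S = disp$S,
                 feature_names = nms, lambda1 = lambda1),
            class = "selection_problem")
}

#' Center each class block on its own column means
#'
#' @param A samples x features matrix.
#' @param y -1/+1 labels (+1 = class 1).
#' @return list with `C1` and `C2`, the centered class blocks (each has
#'   zero column means).
#' @export
center_classes <- function(A, y) {
  A <- as.matrix(A)
  if (sum(y == 1) < 1L || sum(y == -1) < 1L) stop("a class is empty")
  A1 <- A[y == 1, , drop = FALSE]
  A2 <- A[y == -1, , drop = FALSE]
  list(C1 = sweep(A1, 2L, colMeans(A1)),
       C2 = sweep(A2, 2L, colMeans(A2)))
}

#' Intra-class dispersion and its per-feature diagonals
#'
#' Total dispersion `S = ||C1||_F^2 + ||C2||_F^2`; the diagonals
#' `Dk[j] = ||Ck[, j]||_2^2` are the per-feature within-class scatters
#' entering the model's quadratic penalty.
#'
#' @param C1,C2 centered class blocks from [center_classes()].
#' @return list with scalar `S` and numeric vectors `D1`, `D2`.
#' @export
intra_class_dispersion <- function(C1, C2) {
  D1 <- colSums(C1^2)
  D2 <- colSums(C2^2)
  list(S = sum(D1) + sum(D2), D1 = D1, D2 = D2)
}

# combined quadratic form 2 A'A + (2/n1) D1 + (2/n2) D2 of the smooth part
.smooth_quadratic <- function(problem, use_dispersion = TRUE) {
  Q <- 2 * crossprod(problem$A)
  if (use_dispersion)
    diag(Q) <- diag(Q) + 2 * problem$D1 / problem$n1 +
      2 * problem$D2 / problem$n2
  Q
}

#' Objective, gradient and Lipschitz constant of the smooth part
#'
#' `objective()` evaluates the full penalized objective at `b`;
#' `gradient()` returns the exact gradient of the smooth part
#' `f(b) = ||Ab - Y||^2 + sum_j D1[j] b_j^2 / n1 + sum_j D2[j] b_j^2 / n2`,
#' namely `(2 A'A + (2/n1) D1 + (2/n2) D2) b - 2 A'Y`; `lipschitz()`
#' returns the largest eigenvalue of that quadratic form, the minimal
#' Lipschitz constant of the gradient and hence the ISTA step size 1/L.
#'
#' @param problem a `selection_problem`.
#' @param b coefficient vector (length = number of features).
#' @param lambda1 L1 penalty used in `objective` (default the problem's).
#' @param use_dispersion set `FALSE` to evaluate the plain Lasso smooth
#'   part (dispersion terms zeroed).
#' @return `objective`: scalar; `gradient`: numeric(p); `lipschitz`:
#'   scalar L > 0.
#' @name selection_objective
NULL

#' @rdname selection_objective
#' @export
objective <- function(problem, b, lambda1 = problem$lambda1,
                      use_dispersion = TRUE) {
  if (is.null(lambda1)) lambda1 <- 0
  r <- problem$A %*% b - problem$y
  f <- sum(r^2)
  if (use_dispersion)
    f <- f + sum(problem$D1 * b^2) / problem$n1 +
      sum(problem$D2 * b^2) / problem$n2
  f + lambda1 * sum(abs(b))
}

#' @rdname selection_objective
#' @export
gradient <- function(problem, b, use_dispersion = TRUE) {
  g <- 2 * as.numeric(crossprod(problem$A, problem$A %*% b - problem$y))
  if (use_dispersion)
    g <- g + (2 * problem$D1 / problem$n1 + 2 * problem$D2 / problem$n2) * b
  g
}

#' @rdname selection_objective
#' @export
lipschitz <- function(problem, use_dispersion = TRUE) {
  Q <- .smooth_quadratic(problem, use_dispersion)
  max(eigen(Q, symmetric = TRUE, only.values = TRUE)$values)
}

#' Componentwise soft-thresholding operator
#'
#' `sign(v) * pmax(|v| - t, 0)`, the proximal operator of `t * ||.||_1`.
#'
#' @param v numeric vector.
#' @param t nonnegative threshold.
#' @return numeric vector of the same length.
#' @export
soft_threshold <- function(v, t) {
  stopifnot(t >= 0)
  sign(v) * pmax(abs(v) - t, 0)
}

#' Solve the dispersion-penalized selection model by ISTA
#'
#' Proximal gradient iteration from `b0 = 0`:
#' `b_{k+1} = soft_threshold(b_k - (1/L) grad f(b_k), lambda1 / L)`,
#' stopping when `||b_{k+1} - b_k||_2 < tol` or `max_iter` is reached.
#' The objective trajectory is nonincreasing and the solver is fully
#' deterministic.
#'
#' `threshold_scale = "absolute"` applies the literal threshold `lambda1`
#' inside the proximal step instead of `lambda1 / L` (equivalent to
#' solving with penalty `L * lambda1`); it is provided for comparison
#' only.
#'
#' @inheritParams selection_objective
#' @param lambda1 nonnegative L1 penalty (defaults to the problem's).
#' @param tol convergence tolerance on the iterate step norm
#'   (default 1e-6).
#' @param max_iter iteration cap (default 10000).
#' @param threshold_scale `"lipschitz"` (standard proximal step,
#'   default) or `"absolute"`.
#' @return object of class `selection_result`: list with named
#'   coefficient vector `b`, `support` (indices with |b| > 1e-8), `L`,
#'   `iterations`, `objective` (trajectory including the starting value),
#'   `converged`, `lambda1`.
#' @export
ista_solve <- function(problem, lambda1 = problem$lambda1, tol = 1e-6,
                       max_iter = 10000L, use_dispersion = TRUE,
                       threshold_scale = c("lipschitz", "absolute")) {
  threshold_scale <- match.arg(threshold_scale)
  if (is.null(lambda1)) stop("`lambda1` must be given (or see choose_lambda)")
  stopifnot(lambda1 >= 0)
  Q <- .smooth_quadratic(problem, use_dispersion)
  L <- max(eigen(Q, symmetric = TRUE, only.values = TRUE)$values)
  aty2 <- 2 * as.numeric(crossprod(problem$A, problem$y))
  p <- ncol(problem$A)
  thr <- if (threshold_scale == "lipschitz") lambda1 / L else lambda1
  b <- numeric(p)
  obj <- objective(problem, b, lambda1, use_dispersion)
  converged <- FALSE
  iter <- 0L
  while (iter < max_iter) {
    iter <- iter + 1L
    g <- as.numeric(Q %*% b) - aty2
    b_new <- soft_threshold(b - g / L, thr)
    obj <- c(obj, objective(problem, b_new, lambda1, use_dispersion))
    if (sqrt(sum((b_new - b)^2)) < tol) {
      b <- b_new
      converged <- TRUE
      break
    }
    b <- b_new
  }
  if (!converged)
    warning(sprintf("ISTA did not converge within %d iterations", max_iter))
  names(b) <- problem$feature_names
  structure(list(b = b, support = which(abs(b) > 1e-8), L = L,
                 iterations = iter, objective = obj, converged = converged,
                 lambda1 = lambda1),
            class = "selection_result")
}

#' Plain Lasso fit as the zero-dispersion special case
#'
#' Runs the same ISTA pipeline with both dispersion diagonals zeroed,
#' i.e. minimizes `||Ab - Y||^2 + lambda1 ||b||_1`.
#'
#' @inheritParams ista_solve
#' @return a `selection_result` (see [ista_solve()]).
#' @export
lasso_fit <- function(problem, lambda1 = problem$lambda1, tol = 1e-6,
                      max_iter = 10000L) {
  ista_solve(problem, lambda1 = lambda1, tol = tol, max_iter = max_iter,
             use_dispersion = FALSE)
}

#' Ranked nonzero coefficients of a solved selection model
#'
#' @param result a `selection_result`.
#' @param names optional feature names (defaults to the names of `b`).
#' @return data.frame with `feature` and `coefficient`, sorted by
#'   decreasing |coefficient|; empty (with a warning) if no coefficient
#'   is nonzero.
#' @export
select_features <- function(result, names = NULL) {
  b <- result$b
  if (is.null(names)) names <- names(b)
  if (is.null(names)) names <- paste0("f", seq_along(b))
  keep <- which(abs(b) > 1e-8)
  if (length(keep) == 0L) {
    warning("empty support: no feature has a nonzero coefficient")
    return(data.frame(feature = character(0), coefficient = numeric(0)))
  }
  ord <- keep[order(abs(b[keep]), decreasing = TRUE)]
  data.frame(feature = names[ord], coefficient = unname(b[ord]),
             row.names = NULL)
}

#' Default L1 penalty selection
#'
#' Solves the model on a 30-point logarithmic grid descending from
#' `lambda_max = max|2 A'Y|` (the smallest penalty with an all-zero
#' solution). Grid values whose support size lies in
#' `[1, floor(max_support_frac * p)]` are candidates; among candidates
#' (deduplicated by identical supports) the one maximizing leave-one-out
#' accuracy of the downstream linear SVM on the training data is chosen.
#' Candidates within one held-out sample (1/n) of the maximum are
#' treated as statistically tied; the midpoint of the tied stretch in
#' grid order is returned, balancing its underfit (over-sparse) and
#' overfit (noise-laden) ends.
#'
#' @inheritParams ista_solve
#' @param n_grid grid size (default 30).
#' @param max_support_frac largest admissible support as a fraction of p
#'   (default 0.6).
#' @param svm_cost linear SVM cost parameter used in the LOOCV score.
#' @param grid_span ratio lambda_max / lambda_min of the grid
#'   (default 1000).
#' @return list with `lambda1` (chosen value), `accuracy` (its LOOCV
#'   accuracy), and `grid` (data.frame of lambda, support size, accuracy).
#' @export
choose_lambda <- function(problem, n_grid = 30L, max_support_frac = 0.6,
                          svm_cost = 1, grid_span = 1000,
                          use_dispersion = TRUE, tol = 1e-6,
                          max_iter = 10000L) {
  p <- ncol(problem$A)
  lam_max <- max(abs(2 * as.numeric(crossprod(problem$A, problem$y))))
  lams <- exp(seq(log(lam_max), log(lam_max / grid_span),
                  length.out = n_grid))
  max_supp <- max(1L, floor(max_support_frac * p))
  supports <- vector("list", n_grid)
  sizes <- integer(n_grid)
  for (k in seq_len(n_grid)) {
    fit <- ista_solve(problem, lambda1 = lams[k], tol = tol,
                      max_iter = max_iter, use_dispersion = use_dispersion)
    supports[[k]] <- fit$support
    sizes[k] <- length(fit$support)
  }
  cand <- which(sizes >= 1L & sizes <= max_supp)
  if (length(cand) == 0L) {
    warning("no grid value gave an admissible support; using the sparsest ",
            "nonempty solution")
    cand <- which(sizes >= 1L)
    if (length(cand) == 0L) stop("all grid solutions are empty")
    cand <- cand[which.min(sizes[cand])]
  }
  key <- vapply(supports, function(s) paste(s, collapse = ","), character(1))
  acc <- rep(NA_real_, n_grid)
  yfac <- factor(ifelse(problem$y == 1, "pos", "neg"),
                 levels = c("neg", "pos"))
  n <- nrow(problem$A)
  for (k in cand) {
    dup <- cand[cand < k & key[cand] == key[k]]
    if (length(dup) > 0L) {
      acc[k] <- acc[dup[1L]]
    } else {
      # libsvm's built-in leave-one-out (cross = n) scores the tuning
      # grid; columns of A are already standardized problem-wide
      fit <- e1071::svm(problem$A[, supports[[k]], drop = FALSE], yfac,
                        kernel = "linear", cost = svm_cost, scale = FALSE,
                        cross = n)
      acc[k] <- fit$tot.accuracy / 100
    }
  }
  # leave-one-out accuracy moves in steps of 1/n, so candidates within
  # one held-out sample of the maximum are statistically tied. The tied
  # stretch typically runs from an underfit (too sparse) to an overfit
  # (noise-laden) end of the path; its midpoint in grid order balances
  # the two, rounding toward the denser side.
  tied <- sort(cand[acc[cand] >= max(acc[cand]) - 1 / n - 1e-12])
  best <- tied[ceiling((length(tied) + 1) / 2)]
  list(lambda1 = lams[best], accuracy = acc[best],
       grid = data.frame(lambda = lams, support_size = sizes,
                         accuracy = acc))
}
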