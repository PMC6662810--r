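# Independent brute-force oracles and geometric fixtures used across the
# suite. Everything here is deliberately written as literal loops /
# closed forms, independent of the package's vectorized implementations.

# ---- fixtures ------------------------------------------------------------

rasterize_disk <- function(radius, pad = 10L) {
  n <- 2L * radius + 2L * pad + 1L
  ctr <- (n + 1) / 2
  outer(1:n, 1:n, function(r, c) (r - ctr)^2 + (c - ctr)^2 <= radius^2)
}

rasterize_square <- function(side, pad = 10L) {
  n <- side + 2L * pad
  m <- matrix(FALSE, n, n)
  m[(pad + 1L):(pad + side), (pad + 1L):(pad + side)] <- TRUE
  m
}

rasterize_rect <- function(h, w, pad = 10L) {
  m <- matrix(FALSE, h + 2L * pad, w + 2L * pad)
  m[(pad + 1L):(pad + h), (pad + 1L):(pad + w)] <- TRUE
  m
}

# a fixed 4 x 4 grid with 3 gray levels (values are already quantized)
toy_grid <- function() {
  matrix(c(0L, 0L, 1L, 2L,
           1L, 1L, 2L, 2L,
           0L, 2L, 2L, 1L,
           0L, 0L, 1L, 0L), nrow = 4L, byrow = TRUE)
}

toy_qimage <- function() {
  structure(list(pixels = toy_grid(), levels = 3L, mask = NULL),
            class = "quantized_image")
}

# irregular blob for invariance checks: thresholded smoothed noise
random_blob <- function(seed, n = 48L) {
  set.seed(seed)
  f <- matrix(stats::rnorm(n * n), n, n)
  k <- stats::dnorm(-6:6, sd = 3); k <- k / sum(k)
  sm <- stats::filter(rbind(f[rep(1, 6), ], f, f[rep(n, 6), ]), k)
  sm <- matrix(sm[7:(6 + n), ], n, n)
  sm <- t(stats::filter(rbind(t(sm)[rep(1, 6), ], t(sm), t(sm)[rep(n, 6), ]), k)[7:(6 + n), ])
  m <- sm > stats::quantile(sm, 0.7)
  # keep the largest 8-connected component only
  lb <- trabtex::label_components(m, min_area = 1L)
  lb == 1L
}

# ---- GLCM oracle ---------------------------------------------------------

# brute-force symmetric normalized co-occurrence matrix by explicit pair
# enumeration in both orders
glcm_oracle <- function(px, G, d, direction) {
  offs <- list("0" = c(0, d), "45" = c(-d, d),
               "90" = c(-d, 0), "135" = c(-d, -d))[[as.character(direction)]]
  P <- matrix(0, G, G)
  nr <- nrow(px); nc <- ncol(px)
  for (r in seq_len(nr)) for (c in seq_len(nc)) {
    r2 <- r + offs[1]; c2 <- c + offs[2]
    if (r2 >= 1 && r2 <= nr && c2 >= 1 && c2 <= nc) {
      a <- px[r, c] + 1L; b <- px[r2, c2] + 1L
      P[a, b] <- P[a, b] + 1
      P[b, a] <- P[b, a] + 1
    }
  }
  P / sum(P)
}

# literal double-loop Haralick summations over the matrix cells
haralick_oracle <- function(P) {
  G <- nrow(P)
  lev <- 0:(G - 1)
  px <- rowSums(P)
  mu <- sum(lev * px)
  sig2 <- sum((lev - mu)^2 * px)
  asm <- 0; con <- 0; ent <- 0; idm <- 0; vr <- 0; cor_num <- 0
  psum <- numeric(2 * G - 1); pdiff <- numeric(G)
  for (i in 1:G) for (j in 1:G) {
    p <- P[i, j]
    asm <- asm + p^2
    con <- con + (i - j)^2 * p
    if (p > 0) ent <- ent - p * log(p)
    idm <- idm + p / (1 + (i - j)^2)
    vr <- vr + ((i - 1) - mu)^2 * p
    cor_num <- cor_num + (i - 1) * (j - 1) * p
    psum[i + j - 1] <- psum[i + j - 1] + p
    pdiff[abs(i - j) + 1] <- pdiff[abs(i - j) + 1] + p
  }
  ks <- 0:(2 * G - 2); kd <- 0:(G - 1)
  sa <- sum(ks * psum)
  sv <- sum((ks - sa)^2 * psum)
  se <- -sum(ifelse(psum > 0, psum * log(psum), 0))
  de <- -sum(ifelse(pdiff > 0, pdiff * log(pdiff), 0))
  da <- sum(kd * pdiff)
  dv <- sum((kd - da)^2 * pdiff)
  c(angular_second_moment = asm, contrast = con,
    correlation = if (sig2 > 0) (cor_num - mu^2) / sig2 else NA_real_,
    variance = vr, sum_of_variance = sv, mean_sum = sa, entropy = ent,
    sum_entropy = se, entropy_difference = de, residual_variance = dv,
    inverse_difference_moment = idm)
}

# ---- GLRLM oracle --------------------------------------------------------

# run-length counting by explicit line walking
glrlm_oracle <- function(px, G, direction) {
  nr <- nrow(px); nc <- ncol(px)
  lines <- switch(as.character(direction),
    "0" = lapply(seq_len(nr), function(r) px[r, ]),
    "90" = lapply(seq_len(nc), function(c) px[, c]),
    "45" = lapply(2:(nr + nc), function(s) {
      rs <- max(1, s - nc):min(nr, s - 1)
      px[cbind(rs, s - rs)]
    }),
    "135" = lapply((1 - nc):(nr - 1), function(dd) {
      rs <- max(1, 1 + dd):min(nr, nc + dd)
      px[cbind(rs, rs - dd)]
    }))
  runs <- list()
  for (ln in lines) {
    i <- 1L
    while (i <= length(ln)) {
      j <- i
      while (j < length(ln) && ln[j + 1L] == ln[i]) j <- j + 1L
      runs[[length(runs) + 1L]] <- c(ln[i], j - i + 1L)
      i <- j + 1L
    }
  }
  runs <- do.call(rbind, runs)
  R <- matrix(0L, G, max(runs[, 2]))
  for (k in seq_len(nrow(runs)))
    R[runs[k, 1] + 1L, runs[k, 2]] <- R[runs[k, 1] + 1L, runs[k, 2]] + 1L
  R
}

glrlm_features_oracle <- function(R) {
  nr <- sum(R)
  sre <- 0; lre <- 0
  for (g in seq_len(nrow(R))) for (r in seq_len(ncol(R))) {
    sre <- sre + R[g, r] / r^2
    lre <- lre + R[g, r] * r^2
  }
  c(run_length_nonuniformity = sum(colSums(R)^2) / nr,
    grey_level_nonuniformity = sum(rowSums(R)^2) / nr,
    short_run_emphasis = sre / nr, long_run_emphasis = lre / nr)
}

# ---- Hu moment oracle ----------------------------------------------------

# raw-moment summation over every pixel with explicit loops
hu_oracle <- function(comp) {
  idx <- unname(which(comp != 0, arr.ind = TRUE))
  m <- function(p, q) {
    s <- 0
    for (k in seq_len(nrow(idx)))
      s <- s + idx[k, 2]^p * idx[k, 1]^q
    s
  }
  m00 <- m(0, 0); xb <- m(1, 0) / m00; yb <- m(0, 1) / m00
  mu <- function(p, q) {
    s <- 0
    for (k in seq_len(nrow(idx)))
      s <- s + (idx[k, 2] - xb)^p * (idx[k, 1] - yb)^q
    s
  }
  eta <- function(p, q) mu(p, q) / m00^(1 + (p + q) / 2)
  e20 <- eta(2, 0); e02 <- eta(0, 2); e11 <- eta(1, 1)
  e30 <- eta(3, 0); e03 <- eta(0, 3); e21 <- eta(2, 1); e12 <- eta(1, 2)
  a <- e30 + e12; b <- e21 + e03
  c1 <- e30 - 3 * e12; c2 <- 3 * e21 - e03
  c(hu1 = e20 + e02,
    hu2 = (e20 - e02)^2 + 4 * e11^2,
    hu3 = c1^2 + c2^2,
    hu4 = a^2 + b^2,
    hu5 = c1 * a * (a^2 - 3 * b^2) + c2 * b * (3 * a^2 - b^2),
    hu6 = (e20 - e02) * (a^2 - b^2) + 4 * e11 * a * b,
    hu7 = c2 * a * (a^2 - 3 * b^2) - c1 * b * (3 * a^2 - b^2))
}

# small labeled random selection problem for solver tests
random_problem <- function(seed, n = 40L, p = 10L, lambda1 = NULL,
                           standardize = TRUE) {
  set.seed(seed)
  A <- matrix(stats::rnorm(n * p), n, p)
  y <- rep(c(1, -1), length.out = n)
  A[y == 1, 1:3] <- A[y == 1, 1:3] + 0.8
  selection_problem(A, y, lambda1 = lambda1, standardize = standardize)
}
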