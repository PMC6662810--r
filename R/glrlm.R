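#' Gray-level run-length matrix (GLRLM)
#'
#' Counts maximal runs of equal gray level along unit steps of one of the
#' four canonical directions. Entry (g, r) is the number of runs of level
#' g-1 with length r. Each in-mask pixel belongs to exactly one run per
#' direction; masked-out pixels break runs and are not counted.
#'
#' @inheritParams compute_glcm
#' @return object of class `glrlm`: list with `counts` (G x Rmax integer
#'   matrix), `direction`, `levels`, `n_runs`, `n_pixels`.
#' @references Galloway MM (1975) Texture analysis using gray level run
#'   lengths. Comput Graphics Image Process 4:172-179.
#' @export
compute_glrlm <- function(qimage, direction = "0") {
  stopifnot(inherits(qimage, "quantized_image"))
  px <- qimage$pixels
  if (!is.null(qimage$mask)) {
    if (!any(qimage$mask)) stop("`mask` excludes every pixel (degenerate input)")
    px[!qimage$mask] <- -1L               # sentinel: breaks runs, dropped later
  }
  nr <- nrow(px); nc <- ncol(px)
  dir <- as.character(sub("^deg", "", direction))
  # concatenate all scan lines of the direction into one vector, with a
  # -2 sentinel between lines so runs cannot cross line boundaries; a
  # single vectorized change-point pass then yields every run at once
  v <- switch(dir,
    "0"   = as.vector(rbind(t(px), -2L)),          # rows, left to right
    "90"  = as.vector(rbind(px, -2L)),             # columns
    "45"  = unlist(lapply(split(px, row(px) + col(px)),  # anti-diagonals
                          function(x) c(x, -2L)), use.names = FALSE),
    "135" = unlist(lapply(split(px, row(px) - col(px)),  # diagonals
                          function(x) c(x, -2L)), use.names = FALSE),
    stop("`direction` must be one of 0, 45, 90, 135"))
  n <- length(v)
  ends <- c(which(v[-1L] != v[-n]), n)
  lens <- diff(c(0L, ends))
  vals <- v[ends]
  keep <- vals >= 0L
  vals <- vals[keep]; lens <- lens[keep]
  G <- qimage$levels
  if (length(vals) == 0L) stop("no runs found (degenerate input)")
  rmax <- max(lens)
  cnt <- matrix(tabulate((lens - 1L) * G + vals + 1L, nbins = G * rmax),
                G, rmax)
  structure(list(counts = cnt, direction = dir, levels = G,
                 n_runs = length(vals), n_pixels = sum(lens)),
            class = "glrlm")
}

#' Run-length texture parameters of a GLRLM
#'
#' The four run-length parameters, with N_r the total number of runs and
#' R(g, r) the run counts:
#' \describe{
#'   \item{short_run_emphasis}{(1/N_r) sum R(g, r) / r^2}
#'   \item{long_run_emphasis}{(1/N_r) sum R(g, r) r^2}
#'   \item{grey_level_nonuniformity}{(1/N_r) sum_g (sum_r R(g, r))^2}
#'   \item{run_length_nonuniformity}{(1/N_r) sum_r (sum_g R(g, r))^2}
#' }
#'
#' @param rlm a `glrlm` object from [compute_glrlm()].
#' @return named numeric vector of length 4 (names in
#'   [glrlm_parameter_names()] order).
#' @export
glrlm_features <- function(rlm) {
  stopifnot(inherits(rlm, "glrlm"))
  R <- rlm$counts
  nr <- sum(R)
  if (nr == 0L) stop("empty run-length matrix (degenerate input)")
  rr <- matrix(seq_len(ncol(R)), nrow(R), ncol(R), byrow = TRUE)
  c(
    run_length_nonuniformity = sum(colSums(R)^2) / nr,
    grey_level_nonuniformity = sum(rowSums(R)^2) / nr,
    short_run_emphasis = sum(R / rr^2) / nr,
    long_run_emphasis = sum(R * rr^2) / nr
  )
}
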