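#' Label connected trabecular regions in a binary mask
#'
#' 8-connected component labeling (diagonal contacts join regions),
#' discarding components smaller than `min_area` pixels. Labels are
#' renumbered consecutively by decreasing area.
#'
#' @param mask logical or 0/1 matrix; nonzero marks foreground.
#' @param min_area minimum retained component area in pixels (default 20);
#'   smaller speckles are typically segmentation noise at low magnification.
#' @return integer matrix of labels (0 = background).
#' @export
label_components <- function(mask, min_area = 20L) {
  m <- matrix(as.numeric(mask != 0), nrow(mask), ncol(mask))
  lb <- EBImage::imageData(EBImage::bwlabel(m))
  lb <- matrix(as.integer(lb), nrow(m), ncol(m))
  nmax <- max(lb)
  if (nmax == 0L) return(lb)
  # bwlabel is 4-connected; union labels across diagonal contacts
  parent <- seq_len(nmax)
  find <- function(a) { while (parent[a] != a) a <- parent[a] <- parent[parent[a]]; a }
  nr <- nrow(lb); nc <- ncol(lb)
  pairs <- rbind(
    cbind(as.vector(lb[-nr, -nc]), as.vector(lb[-1L, -1L])),   # down-right
    cbind(as.vector(lb[-nr, -1L]), as.vector(lb[-1L, -nc]))    # down-left
  )
  pairs <- unique(pairs[pairs[, 1L] > 0L & pairs[, 2L] > 0L &
                          pairs[, 1L] != pairs[, 2L], , drop = FALSE])
  for (k in seq_len(nrow(pairs))) {
    ra <- find(pairs[k, 1L]); rb <- find(pairs[k, 2L])
    if (ra != rb) parent[max(ra, rb)] <- min(ra, rb)
  }
  root <- vapply(seq_len(nmax), find, integer(1))
  lb[lb > 0L] <- root[lb[lb > 0L]]
  areas <- tabulate(lb[lb > 0L], nbins = nmax)
  keep <- which(areas >= min_area)
  relab <- integer(nmax)
  relab[keep[order(areas[keep], decreasing = TRUE)]] <-
    seq_along(keep)
  lb[lb > 0L] <- relab[lb[lb > 0L]]
  lb
}

# outer boundary chain (pixel centers, 1-based (row, col)) of the single
# region marked in a logical matrix
.component_contour <- function(comp) {
  oc <- EBImage::ocontour(matrix(as.numeric(comp), nrow(comp), ncol(comp)))
  if (length(oc) == 0L) stop("empty component")
  pts <- oc[[1L]] + 1L       # ocontour is 0-based
  matrix(as.numeric(pts), nrow(pts), 2L)
}

#' Dimensionless shape ratios of one trabecular region
#'
#' Computes the six scale-free shape parameters of a single connected
#' region:
#' \describe{
#'   \item{solidity}{area / convex hull area}
#'   \item{regional_density}{area / perimeter^2 (shape factor)}
#'   \item{correction_rate}{maximum inscribed circle diameter / minimum
#'     enclosing circle diameter}
#'   \item{convexity}{convex hull perimeter / perimeter}
#'   \item{roundness}{area / (maximum Feret diameter)^2}
#'   \item{length_width_ratio}{long / short side of the minimum-area
#'     rotated bounding rectangle}
#' }
#' Area is the foreground pixel count (holes are not filled). The
#' perimeter is the bias-corrected length of the traced 8-connected outer
#' boundary chain; solidity, convexity and correction_rate are clamped at
#' 1 where discretization would push the ratio marginally above it.
#'
#' @param component logical or 0/1 matrix containing a single connected
#'   region (8-connectivity).
#' @return named numeric(6).
#' @export
shape_ratios <- function(component) {
  comp <- component != 0
  .shape_ratios_core(comp, .component_contour(comp))
}

# core computation given the region mask and its outer boundary chain
# (pixel centers, 1-based, same coordinate frame as `comp`)
.shape_ratios_core <- function(comp, contour) {
  area <- sum(comp)
  if (area == 0L) stop("empty component")
  perim <- chain_perimeter(contour)
  h <- grDevices::chull(contour)
  hull <- contour[h, , drop = FALSE]
  hull_area <- polygon_area(hull)
  if (hull_area <= 0 || perim <= 0)
    stop("degenerate (line-like) component")
  hull_perim <- polygon_perimeter(hull)
  dm <- EBImage::imageData(EBImage::distmap(.pad(comp)))
  r_in <- max(dm) - 0.5
  mec <- min_enclosing_circle(hull)
  r_out <- mec[3L] + 0.5
  feret <- max_feret(hull)
  rect <- min_area_rect(hull)
  c(
    solidity = min(area / hull_area, 1),
    regional_density = area / perim^2,
    correction_rate = min(max(r_in, 0) / r_out, 1),
    convexity = min(hull_perim / perim, 1),
    roundness = area / feret^2,
    length_width_ratio = (rect[1L] + 1) / (rect[2L] + 1)
  )
}

.pad <- function(comp) {
  out <- matrix(0, nrow(comp) + 2L, ncol(comp) + 2L)
  out[2:(nrow(comp) + 1L), 2:(ncol(comp) + 1L)] <- comp
  out
}

#' Hu invariant moments of a binary region
#'
#' The seven moment invariants of Hu (1962), computed from the normalized
#' central moments of the binary silhouette (every foreground pixel
#' weighted 1). phi1..phi6 are invariant to translation, scale and
#' rotation; phi7 additionally flips sign under mirror reflection.
#'
#' @param component logical or 0/1 matrix with at least one foreground
#'   pixel.
#' @return named numeric(7): `hu1`..`hu7`.
#' @export
hu_moments <- function(component) {
  idx <- which(component != 0, arr.ind = TRUE)
  if (nrow(idx) == 0L) stop("empty component")
  x <- idx[, 2L]; y <- idx[, 1L]
  m00 <- length(x)
  xb <- mean(x); yb <- mean(y)
  dx <- x - xb; dy <- y - yb
  mu <- function(p, q) sum(dx^p * dy^q)
  eta <- function(p, q) mu(p, q) / m00^(1 + (p + q) / 2)
  e20 <- eta(2, 0); e02 <- eta(0, 2); e11 <- eta(1, 1)
  e30 <- eta(3, 0); e03 <- eta(0, 3); e21 <- eta(2, 1); e12 <- eta(1, 2)
  a <- e30 + e12; b <- e21 + e03
  c1 <- e30 - 3 * e12; c2 <- 3 * e21 - e03
  c(
    hu1 = e20 + e02,
    hu2 = (e20 - e02)^2 + 4 * e11^2,
    hu3 = c1^2 + c2^2,
    hu4 = a^2 + b^2,
    hu5 = c1 * a * (a^2 - 3 * b^2) + c2 * b * (3 * a^2 - b^2),
    hu6 = (e20 - e02) * (a^2 - b^2) + 4 * e11 * a * b,
    hu7 = c2 * a * (a^2 - 3 * b^2) - c1 * b * (3 * a^2 - b^2)
  )
}

#' Names of the 13 shape parameters, in fixed table order
#' @return character(13).
#' @export
shape_parameter_names <- function() {
  c("solidity", "regional_density", "correction_rate", "convexity",
    "roundness", "length_width_ratio", paste0("hu", 1:7))
}

#' Image-level shape descriptor from a trabecular mask
#'
#' Labels the mask ([label_components()]), computes the 6 shape ratios and
#' 7 Hu moments for every retained component, and aggregates them into one
#' 13-value descriptor per image. Degenerate (line-like) components are
#' skipped with a warning.
#'
#' @param mask binary matrix of trabecular foreground.
#' @param min_area minimum component area in pixels (default 20).
#' @param weighting aggregation across components: `"area"` (area-weighted
#'   mean, default), `"unweighted"` (plain mean), or `"largest"` (largest
#'   component only).
#' @return named numeric(13) in [shape_parameter_names()] order.
#' @export
aggregate_shape <- function(mask, min_area = 20L,
                            weighting = c("area", "unweighted", "largest")) {
  weighting <- match.arg(weighting)
  lb <- label_components(mask, min_area = min_area)
  ncomp <- max(lb)
  if (ncomp == 0L) stop("no retained components (degenerate input)")
  if (weighting == "largest") ncomp <- 1L   # labels sorted by area
  desc <- matrix(NA_real_, ncomp, 13L,
                 dimnames = list(NULL, shape_parameter_names()))
  areas <- numeric(ncomp)
  contours <- EBImage::ocontour(lb)         # one pass for all components
  pix <- which(lb > 0L)
  comp_pix <- split(pix, lb[pix])
  nr <- nrow(lb)
  for (k in seq_len(ncomp)) {
    pk <- comp_pix[[as.character(k)]]
    rows <- (pk - 1L) %% nr + 1L
    cols <- (pk - 1L) %/% nr + 1L
    r0 <- range(rows); c0 <- range(cols)
    sub <- lb[r0[1L]:r0[2L], c0[1L]:c0[2L], drop = FALSE] == k
    cont <- contours[[as.character(k)]]
    cont <- cbind(cont[, 1L] + 2L - r0[1L], cont[, 2L] + 2L - c0[1L])
    areas[k] <- length(pk)
    res <- tryCatch(c(.shape_ratios_core(sub, cont), hu_moments(sub)),
                    error = function(e) {
                      warning(sprintf("component %d skipped: %s",
                                      k, conditionMessage(e)))
                      NULL
                    })
    if (!is.null(res)) desc[k, ] <- res
  }
  ok <- !is.na(desc[, 1L])
  if (!any(ok)) stop("no retained components (all degenerate)")
  desc <- desc[ok, , drop = FALSE]
  w <- switch(weighting,
              area = areas[ok] / sum(areas[ok]),
              unweighted = rep(1 / sum(ok), sum(ok)),
              largest = 1)
  out <- as.numeric(t(desc) %*% w)
  names(out) <- shape_parameter_names()
  out
}
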