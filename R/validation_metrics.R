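## Segmentation validation: average symmetric surface distance (ASSD) and
## relative volumetric difference (RVD), the parametric sweep over the
## growth-parameter grid, and the similarity-rate summary.

#' Surface points of a binary mask
#'
#' All TRUE pixels with at least one FALSE 8-neighbour; the image border
#' counts as FALSE, so mask pixels on the frame edge are surface points.
#'
#' @param mask logical matrix, nonempty.
#' @return integer matrix of (row, col) surface-point coordinates.
#' @export
surfacePoints <- function(mask) {
  if (!any(mask)) stop("degenerate input: empty mask")
  interior <- cpp_erode(mask, 3L)
  idx <- which(mask & !interior, arr.ind = TRUE)
  colnames(idx) <- c("row", "col")
  idx
}

#' Shortest distance from a point to a surface point set
#'
#' @param p numeric \code{c(row, col)}.
#' @param P nonempty matrix of (row, col) surface points.
#' @return Euclidean distance in pixels.
#' @export
pointToSetDistance <- function(p, P) {
  if (is.null(dim(P))) P <- matrix(P, ncol = 2L)
  if (nrow(P) == 0L) stop("surface point set must be nonempty")
  min(sqrt((P[, 1] - p[1])^2 + (P[, 2] - p[2])^2))
}

#' Average symmetric surface distance between two masks
#'
#' Sum of nearest-surface distances taken in both directions between the
#' surface point sets, divided by the total number of surface points:
#' zero for identical surfaces, growing with boundary disagreement.
#'
#' @param S1,S2 nonempty logical matrices (segmentation and reference).
#' @return ASSD in pixels.
#' @export
assd <- function(S1, S2) {
  P1 <- surfacePoints(S1)
  P2 <- surfacePoints(S2)
  sums <- cpp_surface_sums(
    matrix(as.numeric(P1), ncol = 2L),
    matrix(as.numeric(P2), ncol = 2L)
  )
  (sums[1] + sums[2]) / (nrow(P1) + nrow(P2))
}

#' Relative volumetric difference
#'
#' Signed by default: \code{(V1 - V2) / V2} with V the pixel count, so
#' negative values indicate under-segmentation relative to the reference.
#' The unsigned variant |V1 - V2| / ((V1 + V2)/2) is available for
#' comparison.
#'
#' @param S1 segmented mask (logical matrix).
#' @param S2 reference mask (logical matrix, nonempty).
#' @param signed use the signed convention (default TRUE).
#' @return unitless ratio.
#' @export
rvd <- function(S1, S2, signed = TRUE) {
  v1 <- sum(S1)
  v2 <- sum(S2)
  if (v2 == 0) stop("degenerate input: empty reference mask")
  if (signed) (v1 - v2) / v2 else abs(v1 - v2) / ((v1 + v2) / 2)
}

#' Default growth-parameter grid of the parametric study
#'
#' Kernel sizes \{3, 6, 9, 12\}, growth depths \{3, 5, 7, 9\}, upper
#' thresholds \{50, 100, 150, 255\} and lower thresholds \{1, 4, 7\}.
#'
#' @return data.frame with columns kernel, depth, upper, lower (192 rows).
#' @export
defaultSweepGrid <- function() {
  expand.grid(
    kernel = c(3L, 6L, 9L, 12L),
    depth = c(3, 5, 7, 9),
    upper = c(50, 100, 150, 255),
    lower = c(1, 4, 7),
    KEEP.OUT.ATTRS = FALSE
  )
}

#' Parametric sweep of the skin segmenter
#'
#' Runs \code{\link{segmentSkin}} for every grid cell on every
#' (mammogram, breast mask, reference skin mask) triple and averages the
#' RVD and ASSD scores per cell. The best row minimizes |mean RVD| with
#' mean ASSD as tie-break. Failed segmentations are recorded as missing
#' cells, not crashes.
#'
#' @param pairs list of lists with elements \code{mammogram}
#'   (\linkS4class{Mammogram}, cleaned), \code{breastMask}
#'   (\linkS4class{BreastMask}) and \code{reference} (logical matrix).
#' @param grid data.frame with columns kernel, depth, upper, lower
#'   (default \code{\link{defaultSweepGrid}()}).
#' @return data.frame with the grid columns plus \code{mean_rvd},
#'   \code{mean_assd}, \code{n_ok} and a logical \code{best} column.
#' @export
parametricSweep <- function(pairs, grid = defaultSweepGrid()) {
  stopifnot(length(pairs) >= 1L, nrow(grid) >= 1L)
  res <- lapply(seq_len(nrow(grid)), function(g) {
    params <- growthParamsNew(
      upperThreshold = grid$upper[g], lowerThreshold = grid$lower[g],
      erosionKernel = grid$kernel[g], maxDepth = grid$depth[g]
    )
    rvds <- assds <- numeric(0)
    for (p in pairs) {
      sm <- tryCatch(segmentSkin(p$mammogram, p$breastMask, params),
                     error = function(e) NULL)
      if (is.null(sm) || sm@grownCount == 0L) next
      rvds <- c(rvds, rvd(sm@mask, p$reference))
      assds <- c(assds, assd(sm@mask, p$reference))
    }
    data.frame(
      kernel = grid$kernel[g], depth = grid$depth[g],
      upper = grid$upper[g], lower = grid$lower[g],
      mean_rvd = if (length(rvds)) mean(rvds) else NA_real_,
      mean_assd = if (length(assds)) mean(assds) else NA_real_,
      n_ok = length(rvds)
    )
  })
  out <- do.call(rbind, res)
  out$best <- FALSE
  ok <- which(is.finite(out$mean_rvd))
  if (length(ok)) {
    score <- abs(out$mean_rvd[ok])
    cand <- ok[score == min(score)]
    if (length(cand) > 1L) cand <- cand[which.min(out$mean_assd[cand])]
    out$best[cand[1]] <- TRUE
  }
  out
}

#' Similarity-rate summary of validation scores
#'
#' Mean and (population, by default) standard deviation, with the count of
#' scores within one standard deviation of the mean ("acceptable
#' similarity") and beyond it.
#'
#' @param scores numeric vector of at least 2 scores.
#' @param population use the population (n) rather than sample (n-1)
#'   standard deviation.
#' @return list with \code{mean}, \code{sd}, \code{within},
#'   \code{beyond}, \code{within_frac}, \code{beyond_frac}.
#' @export
similarityRate <- function(scores, population = TRUE) {
  n <- length(scores)
  if (n < 2L) stop("need at least 2 scores")
  mu <- mean(scores)
  sdv <- stats::sd(scores)
  if (population) sdv <- sdv * sqrt((n - 1) / n)
  within <- sum(scores >= mu - sdv & scores <= mu + sdv)
  list(
    mean = mu, sd = sdv,
    within = within, beyond = n - within,
    within_frac = within / n, beyond_frac = (n - within) / n
  )
}
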