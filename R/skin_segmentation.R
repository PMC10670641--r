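## Skin-rim segmentation by seeded region growing: Otsu mask -> erosion ->
## border seeds -> zero-padded frame -> conditional breadth-first
## expansion, then a per-border-length thickness statistic compared across
## contralateral sides.

#' Construct seeded region growing parameters
#'
#' @param upperThreshold strict upper bound on |candidate - seed| intensity
#'   difference, 0-255 scale (default 200).
#' @param lowerThreshold strict lower bound on the same difference
#'   (default 1; set 0 to admit identical-intensity neighbours).
#' @param erosionKernel n for the n x n erosion structuring element
#'   (default 9, the parametric-study optimum).
#' @param maxDepth Euclidean growth limit in pixels from the originating
#'   border seed (default 3, the parametric-study optimum).
#' @return a \linkS4class{GrowthParams}.
#' @export
growthParamsNew <- function(upperThreshold = 200, lowerThreshold = 1,
                            erosionKernel = 9L, maxDepth = 3) {
  new("GrowthParams",
      upperThreshold = as.numeric(upperThreshold),
      lowerThreshold = as.numeric(lowerThreshold),
      erosionKernel = as.integer(erosionKernel),
      maxDepth = as.numeric(maxDepth))
}

#' Otsu foreground mask
#'
#' Binarizes at the threshold maximizing between-class variance on a
#' 256-bin histogram. When \code{within} is given, the threshold is fit on
#' those pixels only (used by the skin segmenter to separate the bright
#' skin/dense tissue from darker interior tissue instead of re-finding the
#' breast outline against the dark background).
#'
#' @param image numeric matrix in \[0, 1\] with >= 2 distinct values.
#' @param within optional logical matrix restricting the histogram.
#' @return logical matrix (\code{image > threshold}, FALSE outside
#'   \code{within} when given).
#' @export
otsuMask <- function(image, within = NULL) {
  vals <- if (is.null(within)) as.numeric(image) else image[within]
  if (length(unique(vals)) < 2L) {
    stop("degenerate input: constant image has no Otsu threshold")
  }
  thr <- EBImage::otsu(EBImage::Image(matrix(vals, ncol = 1L)),
                       range = c(0, 1), levels = 256L)
  out <- image > thr
  if (!is.null(within)) out <- out & within
  out
}

#' Binary erosion with an n x n box structuring element
#'
#' Pixels outside the image are background, so erosion shrinks masks at
#' the frame edge. Even kernels anchor the extra row/column toward the
#' bottom-right.
#'
#' @param mask logical matrix.
#' @param kernel integer n >= 1 (n = 1 is the identity).
#' @return logical matrix, a subset of \code{mask}.
#' @export
erodeMask <- function(mask, kernel) {
  stopifnot(kernel >= 1)
  cpp_erode(mask, as.integer(kernel))
}

#' Border seeds: pixels removed by erosion
#'
#' The set difference between a mask and its erosion retains only the
#' boundary band of the breast; these pixels seed the region growth.
#' Seeds are returned in row-major order for deterministic processing.
#'
#' @param mask logical matrix.
#' @param eroded logical matrix, must be a subset of \code{mask}.
#' @return integer matrix of (row, col) seed coordinates.
#' @export
borderSeeds <- function(mask, eroded) {
  if (any(eroded & !mask)) stop("eroded mask must be a subset of mask")
  diffm <- mask & !eroded
  idx <- which(diffm, arr.ind = TRUE)
  if (nrow(idx) == 0L) {
    stop("no seeds: erosion removed nothing (kernel too small or mask degenerate)")
  }
  idx <- idx[order(idx[, 1], idx[, 2]), , drop = FALSE]
  colnames(idx) <- c("row", "col")
  idx
}

#' Pad an image with a one-pixel zero frame
#'
#' Grows an n x m image to (n+2) x (m+2) with a zero border so region
#' growth can evaluate frame-edge pixels without special casing; seed
#' coordinates shift by (+1, +1).
#'
#' @param image numeric matrix.
#' @return padded numeric matrix.
#' @export
padFrame <- function(image) {
  out <- matrix(0, nrow(image) + 2L, ncol(image) + 2L)
  out[2:(nrow(image) + 1L), 2:(ncol(image) + 1L)] <- image
  out
}

#' Seeded region growing
#'
#' Breadth-first expansion over 8-neighbours from the border seeds. A
#' candidate pixel joins the mask iff (i) it is not black
#' (\code{image * 255 > 0}), (ii) its absolute intensity difference from
#' the originating seed of its growth chain lies strictly between the
#' lower and upper thresholds (0-255 scale; a lower threshold of 0
#' disables the lower bound), and (iii) its Euclidean
#' distance from that originating seed is at most \code{maxDepth}. Every
#' pixel is evaluated at most once (a visit counter prevents redundant
#' evaluations); accepted pixels join the frontier attributed to the same
#' originating seed. The frontier is FIFO with row-major seed order and
#' fixed neighbour order N, NE, E, SE, S, SW, W, NW.
#'
#' @param image numeric matrix in \[0, 1\] (typically padded).
#' @param seeds integer matrix of (row, col) seed coordinates.
#' @param params a \linkS4class{GrowthParams}.
#' @return a \linkS4class{SkinMask}; its \code{mask} matches
#'   \code{image}'s shape.
#' @export
growRegion <- function(image, seeds, params = growthParamsNew()) {
  stopifnot(is(params, "GrowthParams"))
  if (is.null(dim(seeds))) seeds <- matrix(seeds, ncol = 2L)
  if (nrow(seeds) == 0L) stop("no seeds: empty seed list")
  seeds <- seeds[order(seeds[, 1], seeds[, 2]), , drop = FALSE]
  storage.mode(seeds) <- "integer"
  res <- cpp_grow(image * 255, seeds,
                  params@upperThreshold, params@lowerThreshold,
                  params@maxDepth)
  new("SkinMask",
      mask = res$mask,
      seedCount = nrow(seeds),
      grownCount = as.integer(sum(res$mask)),
      params = params)
}

#' Segment the breast skin rim
#'
#' Full skin branch on a cleaned, right-oriented mammogram: Otsu mask
#' (fit within the breast mask), erosion, border seeds, zero-padded frame,
#' seeded region growing, and crop back to the original frame.
#'
#' @param m cleaned \linkS4class{Mammogram} (background zeroed).
#' @param bm its \linkS4class{BreastMask}.
#' @param params a \linkS4class{GrowthParams}.
#' @return a \linkS4class{SkinMask}.
#' @export
segmentSkin <- function(m, bm, params = growthParamsNew()) {
  stopifnot(is(m, "Mammogram"), is(bm, "BreastMask"))
  img <- m@pixels
  om <- otsuMask(img, within = bm@mask)
  if (!any(om)) stop("degenerate input: empty Otsu mask")
  er <- erodeMask(om, params@erosionKernel)
  seeds <- borderSeeds(om, er)
  padded <- padFrame(img)
  sm <- growRegion(padded, seeds + 1L, params)
  cropped <- sm@mask[2:(nrow(img) + 1L), 2:(ncol(img) + 1L)]
  new("SkinMask",
      mask = cropped, seedCount = sm@seedCount,
      grownCount = as.integer(sum(cropped)), params = params)
}

#' Breast border length in pixels
#'
#' The number of outline pixels of the hole-filled breast mask, excluding
#' pixels on the image frame (the chest-wall side of a right-oriented
#' breast): the length of the air-skin interface the rim runs along.
#' Texture-induced interior holes do not inflate the estimate because the
#' mask is hole-filled first.
#'
#' @param mask logical breast mask.
#' @return integer border length (>= 1).
#' @export
breastBorderLength <- function(mask) {
  filled <- EBImage::fillHull(matrix(as.integer(mask), nrow(mask))) > 0
  sp <- surfacePoints(filled)
  edge <- sp[, 1] == 1L | sp[, 1] == nrow(mask) |
    sp[, 2] == 1L | sp[, 2] == ncol(mask)
  n <- sum(!edge)
  if (n == 0L) nrow(sp) else n
}

#' Mean skin thickness per unit of border length
#'
#' The grown pixel count divided by the border length: the mean radial
#' extent of the skin band. The statistic is isolated here so alternative
#' thickness definitions can be swapped in.
#'
#' @param sm a nonempty \linkS4class{SkinMask}.
#' @param borderLength breast border length in pixels (> 0), e.g. the
#'   number of breast-mask surface points.
#' @return thickness in pixels.
#' @export
skinThickness <- function(sm, borderLength) {
  stopifnot(is(sm, "SkinMask"))
  if (borderLength <= 0) stop("borderLength must be > 0")
  if (sm@grownCount == 0L) stop("degenerate input: empty skin mask")
  sm@grownCount / borderLength
}

#' Relative contralateral thickness difference
#'
#' \code{|left - right| / max(left, right)}: a symmetric, scale-free
#' difference in \[0, 1\].
#'
#' @param left,right skin thicknesses (>= 0, not both zero).
#' @return unitless relative difference.
#' @export
thicknessDifference <- function(left, right) {
  stopifnot(left >= 0, right >= 0)
  mx <- max(left, right)
  if (mx == 0) stop("both thicknesses are zero")
  abs(left - right) / mx
}

#' Flag skin-thickness asymmetry
#'
#' The flag is raised for a strictly greater relative difference than the
#' threshold (default 0.39, the cohort-mean decision level of the
#' reference study).
#'
#' @param diff relative thickness difference (>= 0).
#' @param threshold decision threshold.
#' @return logical flag.
#' @export
classifySkinAsymmetry <- function(diff, threshold = 0.39) {
  stopifnot(diff >= 0)
  diff > threshold
}
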