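## Annotation removal and orientation standardization. Burned-in
## annotations are small, isolated bright islands; thresholding at the
## calibrated 8-bit level T = 100 followed by largest-connected-component
## selection keeps the breast and drops everything else.

#' Threshold an intensity image on the 8-bit scale
#'
#' A pixel is foreground iff \code{image * 255 > T}. The threshold is
#' expressed on the 0-255 grayscale (default 100, the calibrated
#' annotation-removal constant) even though internal intensities are
#' stored in \[0, 1\].
#'
#' @param image numeric matrix in \[0, 1\].
#' @param T threshold on the 0-255 scale.
#' @return logical matrix.
#' @export
thresholdMask <- function(image, T = 100) {
  stopifnot(is.matrix(image))
  image * 255 > T
}

#' Largest connected component of a binary mask
#'
#' Keeps exactly the pixels of the component with maximal pixel count.
#' Ties are broken deterministically in favour of the component whose
#' lexicographically smallest (row, col) pixel comes first.
#'
#' @param mask logical matrix with at least one TRUE pixel.
#' @param connectivity 4 or 8 (default 8).
#' @return logical matrix containing a single component.
#' @export
largestConnectedComponent <- function(mask, connectivity = 8) {
  stopifnot(connectivity %in% c(4, 8))
  if (!any(mask)) stop("degenerate input: empty mask")
  lab <- cpp_label(mask, as.integer(connectivity))
  sizes <- tabulate(lab[lab > 0L])
  best <- which(sizes == max(sizes))
  ## labels are assigned in row-major order of first encounter, but R
  ## matrices index column-major; recover the row-major-first label
  if (length(best) > 1L) {
    first_key <- vapply(best, function(l) {
      idx <- which(lab == l, arr.ind = TRUE)
      min(idx[, 1] * (ncol(mask) + 1) + idx[, 2])
    }, numeric(1))
    best <- best[which.min(first_key)]
  }
  lab == best[1]
}

#' Standardize breast orientation to face right
#'
#' If the mask's column-wise center of mass lies in the left half of the
#' frame, image and mask are mirrored left-right. The decision is made
#' from mask mass, not from DICOM laterality, because burned-in flips are
#' common; laterality is metadata for reporting only.
#'
#' @param image numeric matrix.
#' @param mask logical matrix, same shape, nonempty.
#' @param laterality ignored by the flip decision; kept for interface
#'   symmetry with the reporting layer.
#' @return list with \code{image}, \code{mask}, \code{flipped}.
#' @export
standardizeOrientation <- function(image, mask, laterality = "UNKNOWN") {
  stopifnot(any(mask))
  colmass <- colSums(mask)
  com <- sum(colmass * seq_along(colmass)) / sum(colmass)
  flipped <- com < (ncol(mask) + 1) / 2
  if (flipped) {
    image <- image[, ncol(image):1, drop = FALSE]
    mask <- mask[, ncol(mask):1, drop = FALSE]
  }
  list(image = image, mask = mask, flipped = flipped)
}

#' Arithmetic-mean centroid of a binary mask
#'
#' @param mask logical matrix, nonempty.
#' @return numeric \code{c(row, col)} in fractional pixels.
#' @export
maskCentroid <- function(mask) {
  idx <- which(mask, arr.ind = TRUE)
  if (nrow(idx) == 0L) stop("degenerate input: empty mask")
  c(mean(idx[, 1]), mean(idx[, 2]))
}

#' Clean a mammogram: remove annotations, orient right, zero background
#'
#' Composition of the preprocessing steps: threshold at \code{T},
#' keep the largest connected component, standardize orientation so the
#' breast faces right, and zero every pixel outside the mask (so that the
#' skin segmenter's "must not be black" condition cleanly excludes
#' background).
#'
#' @param m a \linkS4class{Mammogram}, already normalized (and typically
#'   resized to the standard frame).
#' @param T annotation-removal threshold on the 0-255 scale.
#' @param connectivity component connectivity, 4 or 8.
#' @return list with \code{mammogram} (cleaned \linkS4class{Mammogram}),
#'   \code{mask} (a \linkS4class{BreastMask}) and \code{flipped}.
#' @export
cleanMammogram <- function(m, T = 100, connectivity = 8) {
  stopifnot(is(m, "Mammogram"))
  img <- m@pixels
  fg <- thresholdMask(img, T)
  if (!any(fg)) stop("degenerate input: no foreground above threshold")
  comp <- largestConnectedComponent(fg, connectivity)
  ori <- standardizeOrientation(img, comp, m@laterality)
  img <- ori$image
  comp <- ori$mask
  img[!comp] <- 0
  m@pixels <- img
  bm <- new("BreastMask",
    mask = comp, centroid = maskCentroid(comp),
    area = as.integer(sum(comp)), orientedRight = TRUE
  )
  list(mammogram = m, mask = bm, flipped = ori$flipped)
}
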