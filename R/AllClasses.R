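#' @import methods
#' @importFrom Rcpp sourceCpp
#' @useDynLib MammoAsym, .registration = TRUE
NULL

#' Mammogram: a normalized 2-D mammographic image with acquisition metadata
#'
#' The unit of ingestion for the asymmetry pipeline. Pixel intensities are
#' unitless and normalized to \[0, 1\] (either by VOI LUT windowing or by
#' bit-depth division); the acquisition bit depth and the pre-resize shape
#' are retained so that physical scaling can be reported downstream.
#'
#' @slot pixels numeric matrix of intensities in \[0, 1\].
#' @slot laterality one of \code{"LEFT"}, \code{"RIGHT"}, \code{"UNKNOWN"}.
#' @slot projection one of \code{"CC"}, \code{"MLO"}, \code{"UNKNOWN"}.
#' @slot sourceBitDepth integer, bits per stored pixel (>= 8).
#' @slot originalShape integer vector \code{c(rows, cols)} before any resize.
#' @slot patientID opaque character id (may be empty).
#' @export
setClass("Mammogram",
  representation(
    pixels = "matrix",
    laterality = "character",
    projection = "character",
    sourceBitDepth = "integer",
    originalShape = "integer",
    patientID = "character"
  ),
  prototype(
    laterality = "UNKNOWN", projection = "UNKNOWN",
    sourceBitDepth = 8L, patientID = ""
  )
)

setValidity("Mammogram", function(object) {
  p <- object@pixels
  if (!is.numeric(p) || length(dim(p)) != 2L) {
    return("pixels must be a 2-D numeric matrix")
  }
  rng <- range(p)
  if (rng[1] < -1e-9 || rng[2] > 1 + 1e-9) {
    return("pixel intensities must lie in [0, 1]")
  }
  if (!object@laterality %in% c("LEFT", "RIGHT", "UNKNOWN")) {
    return("laterality must be LEFT, RIGHT or UNKNOWN")
  }
  if (!object@projection %in% c("CC", "MLO", "UNKNOWN")) {
    return("projection must be CC, MLO or UNKNOWN")
  }
  if (object@sourceBitDepth < 8L) return("sourceBitDepth must be >= 8")
  if (length(object@originalShape) != 2L) {
    return("originalShape must be c(rows, cols)")
  }
  TRUE
})

#' BreastMask: single-component breast foreground mask
#'
#' Binary foreground mask of the breast region after annotation removal and
#' orientation standardization, together with its centroid (fractional
#' pixels, \code{(row, col)}) and pixel area.
#'
#' @slot mask logical matrix, exactly one connected component.
#' @slot centroid numeric \code{c(row, col)} in fractional pixels.
#' @slot area integer number of foreground pixels.
#' @slot orientedRight logical; TRUE once column mass lies in the right half.
#' @export
setClass("BreastMask",
  representation(
    mask = "matrix",
    centroid = "numeric",
    area = "integer",
    orientedRight = "logical"
  )
)

setValidity("BreastMask", function(object) {
  m <- object@mask
  if (!is.logical(m) || length(dim(m)) != 2L) {
    return("mask must be a logical matrix")
  }
  if (object@area < 1L) return("area must be >= 1")
  idx <- which(m, arr.ind = TRUE)
  if (nrow(idx) == 0L) return("mask must have at least one TRUE pixel")
  bb <- c(range(idx[, 1]), range(idx[, 2]))
  cen <- object@centroid
  if (cen[1] < bb[1] || cen[1] > bb[2] || cen[2] < bb[3] || cen[2] > bb[4]) {
    return("centroid must lie inside the bounding box of the mask")
  }
  TRUE
})

#' RadialSignature: centroid-to-perimeter distances over angle
#'
#' The ordered angle-to-distance vector that shape comparison operates on:
#' for each angle in \[0, pi\], the distance from the mask centroid to the
#' outermost foreground pixel along the ray at that angle.
#'
#' @slot angles strictly increasing numeric vector spanning \[0, pi\].
#' @slot distances positive numeric vector, same length as \code{angles};
#'   pixels, or unitless after normalization.
#' @slot normalized logical; TRUE once divided by the maximum distance.
#' @slot centroid numeric \code{c(row, col)} the rays were cast from.
#' @export
setClass("RadialSignature",
  representation(
    angles = "numeric",
    distances = "numeric",
    normalized = "logical",
    centroid = "numeric"
  ),
  prototype(normalized = FALSE)
)

setValidity("RadialSignature", function(object) {
  a <- object@angles
  d <- object@distances
  if (length(a) != length(d) || length(a) < 2L) {
    return("angles and distances must have equal length >= 2")
  }
  if (any(diff(a) <= 0)) return("angles must be strictly increasing")
  if (abs(a[1]) > 1e-12 || abs(a[length(a)] - pi) > 1e-9) {
    return("angles must span [0, pi]")
  }
  if (any(d <= 0)) return("all distances must be > 0")
  if (object@normalized && abs(max(d) - 1) > 1e-12) {
    return("normalized signatures must have max(distances) == 1")
  }
  TRUE
})

#' DtwResult: dynamic time warping alignment of two signatures
#'
#' Holds the local cost matrix, the cumulative cost matrix under the
#' right/diagonal/down move set, the backtracked warping path and the
#' normalized asymmetry index (end cost divided by path length).
#'
#' @slot cost n x m matrix of local costs.
#' @slot cumulative n x m matrix of cumulative costs.
#' @slot path k x 2 integer matrix of (i, j) index pairs, 1-based.
#' @slot index unitless asymmetry index in \[0, 1\] for normalized inputs.
#' @export
setClass("DtwResult",
  representation(
    cost = "matrix",
    cumulative = "matrix",
    path = "matrix",
    index = "numeric"
  )
)

setValidity("DtwResult", function(object) {
  p <- object@path
  n <- nrow(object@cost)
  m <- ncol(object@cost)
  if (!all(dim(object@cumulative) == c(n, m))) {
    return("cumulative must match cost dimensions")
  }
  if (ncol(p) != 2L) return("path must have two columns")
  if (any(p[1, ] != c(1L, 1L)) || any(p[nrow(p), ] != c(n, m))) {
    return("path must run from (1,1) to (n,m)")
  }
  if (nrow(p) > 1L) {
    st <- diff(p)
    ok <- (st[, 1] %in% 0:1) & (st[, 2] %in% 0:1) & (st[, 1] + st[, 2] > 0)
    if (!all(ok)) return("path steps must be (+1,0), (0,+1) or (+1,+1)")
  }
  if (any(object@cumulative < object@cost - 1e-12)) {
    return("cumulative must dominate cost elementwise")
  }
  if (object@index < 0) return("index must be >= 0")
  TRUE
})

#' GrowthParams: seeded region growing parameters
#'
#' Tunable parameters of the skin segmenter. Intensity thresholds are on
#' the 0-255 scale; \code{maxDepth} is the Euclidean distance limit (pixels)
#' between a grown pixel and the border seed its growth chain started from.
#' Defaults are the optimum of the parametric study (9 x 9 erosion kernel,
#' 3 pixels deep, intensity window (1, 200)).
#'
#' @slot upperThreshold numeric, strict upper bound on |candidate - seed|.
#' @slot lowerThreshold numeric, strict lower bound on |candidate - seed|.
#' @slot erosionKernel integer n for the n x n structuring element.
#' @slot maxDepth numeric, Euclidean growth limit in pixels.
#' @export
setClass("GrowthParams",
  representation(
    upperThreshold = "numeric",
    lowerThreshold = "numeric",
    erosionKernel = "integer",
    maxDepth = "numeric"
  ),
  prototype(
    upperThreshold = 200, lowerThreshold = 1,
    erosionKernel = 9L, maxDepth = 3
  )
)

setValidity("GrowthParams", function(object) {
  if (object@lowerThreshold < 0 ||
      object@lowerThreshold >= object@upperThreshold ||
      object@upperThreshold > 255) {
    return("need 0 <= lowerThreshold < upperThreshold <= 255")
  }
  if (object@erosionKernel < 1L) return("erosionKernel must be >= 1")
  if (object@maxDepth < 1) return("maxDepth must be >= 1")
  TRUE
})

#' SkinMask: segmented skin rim
#'
#' Output of seeded region growing: the binary skin-rim mask plus the seed
#' and grown pixel counts and the parameters that produced it.
#'
#' @slot mask logical matrix.
#' @slot seedCount integer number of border seeds.
#' @slot grownCount integer number of TRUE pixels in \code{mask}.
#' @slot params the \linkS4class{GrowthParams} used.
#' @export
setClass("SkinMask",
  representation(
    mask = "matrix",
    seedCount = "integer",
    grownCount = "integer",
    params = "GrowthParams"
  )
)

setValidity("SkinMask", function(object) {
  if (!is.logical(object@mask)) return("mask must be logical")
  if (object@grownCount != sum(object@mask)) {
    return("grownCount must equal the number of TRUE pixels")
  }
  TRUE
})

#' PhantomSpec: parametric description of a synthetic mammogram phantom
#'
#' An elliptical breast lobe anchored \code{edgeOffset} pixels inside one
#' lateral image edge (so the chest-wall side is truncated by the frame,
#' as in a compressed craniocaudal view), its boundary radius modulated by
#' a sinusoid over the \[0, pi\] sweep, with a brighter skin rim of
#' controllable width, Gaussian tissue texture, and small bright
#' annotation islands near the background corners. Identical specs render
#' to bit-identical images.
#'
#' @slot imageSize integer, square frame side in pixels.
#' @slot semiAxes numeric \code{c(a, b)}: horizontal (into the image) and
#'   vertical semi-axes in pixels.
#' @slot edgeOffset distance of the lobe center from the flush edge,
#'   pixels (0 gives a half-ellipse).
#' @slot perturbAmplitude sinusoidal boundary perturbation amplitude, pixels.
#' @slot perturbFrequency cycles over the \[0, pi\] sweep.
#' @slot perturbPhase radians.
#' @slot rimWidth skin-rim width in pixels (0 disables the rim).
#' @slot rimIntensity rim intensity in \[0, 1\].
#' @slot interiorIntensity interior tissue intensity in \[0, 1\].
#' @slot textureSd Gaussian texture standard deviation, intensity units.
#' @slot annotationCount number of bright annotation islands.
#' @slot laterality \code{"LEFT"} or \code{"RIGHT"} (which edge the breast
#'   is flush against: LEFT-lateralized phantoms face left).
#' @slot seed integer RNG seed for the texture and annotations.
#' @export
setClass("PhantomSpec",
  representation(
    imageSize = "integer",
    semiAxes = "numeric",
    edgeOffset = "numeric",
    perturbAmplitude = "numeric",
    perturbFrequency = "numeric",
    perturbPhase = "numeric",
    rimWidth = "numeric",
    rimIntensity = "numeric",
    interiorIntensity = "numeric",
    textureSd = "numeric",
    annotationCount = "integer",
    laterality = "character",
    seed = "integer"
  )
)

setValidity("PhantomSpec", function(object) {
  if (object@rimWidth < 0) return("rimWidth must be >= 0")
  if (!(object@rimIntensity > object@interiorIntensity &&
        object@interiorIntensity > 0)) {
    return("need rimIntensity > interiorIntensity > 0")
  }
  if (any(object@semiAxes >= object@imageSize / 2)) {
    return("semi-axes must be < imageSize / 2")
  }
  if (object@edgeOffset < 0 ||
      object@edgeOffset + object@semiAxes[1] >= object@imageSize) {
    return("edgeOffset must be >= 0 and keep the lobe inside the frame")
  }
  if (!object@laterality %in% c("LEFT", "RIGHT")) {
    return("laterality must be LEFT or RIGHT")
  }
  TRUE
})

## ---- generics and accessors -------------------------------------------

#' @describeIn Mammogram-class pixel intensity matrix
#' @param object,x a MammoAsym S4 object
#' @export
setGeneric("pixelData", function(x) standardGeneric("pixelData"))
#' @export
setMethod("pixelData", "Mammogram", function(x) x@pixels)

#' @export
setGeneric("laterality", function(x) standardGeneric("laterality"))
#' @export
setMethod("laterality", "Mammogram", function(x) x@laterality)
#' @export
setMethod("laterality", "PhantomSpec", function(x) x@laterality)

#' @export
setGeneric("projection", function(x) standardGeneric("projection"))
#' @export
setMethod("projection", "Mammogram", function(x) x@projection)

#' @export
setGeneric("sourceBitDepth", function(x) standardGeneric("sourceBitDepth"))
#' @export
setMethod("sourceBitDepth", "Mammogram", function(x) x@sourceBitDepth)

#' Extract the logical mask matrix from a mask-bearing object
#' @param x a \linkS4class{BreastMask} or \linkS4class{SkinMask}
#' @export
setGeneric("maskArray", function(x) standardGeneric("maskArray"))
#' @export
setMethod("maskArray", "BreastMask", function(x) x@mask)
#' @export
setMethod("maskArray", "SkinMask", function(x) x@mask)

#' @export
setGeneric("centroid", function(x) standardGeneric("centroid"))
#' @export
setMethod("centroid", "BreastMask", function(x) x@centroid)
#' @export
setMethod("centroid", "RadialSignature", function(x) x@centroid)

#' @export
setGeneric("signatureAngles", function(x) standardGeneric("signatureAngles"))
#' @export
setMethod("signatureAngles", "RadialSignature", function(x) x@angles)

#' @export
setGeneric("signatureDistances",
           function(x) standardGeneric("signatureDistances"))
#' @export
setMethod("signatureDistances", "RadialSignature", function(x) x@distances)

#' @export
setGeneric("isNormalized", function(x) standardGeneric("isNormalized"))
#' @export
setMethod("isNormalized", "RadialSignature", function(x) x@normalized)

#' @export
setGeneric("dtwIndexValue", function(x) standardGeneric("dtwIndexValue"))
#' @export
setMethod("dtwIndexValue", "DtwResult", function(x) x@index)

#' @export
setGeneric("warpingPath", function(x) standardGeneric("warpingPath"))
#' @export
setMethod("warpingPath", "DtwResult", function(x) x@path)

#' @export
setGeneric("seedCount", function(x) standardGeneric("seedCount"))
#' @export
setMethod("seedCount", "SkinMask", function(x) x@seedCount)

#' @export
setGeneric("grownCount", function(x) standardGeneric("grownCount"))
#' @export
setMethod("grownCount", "SkinMask", function(x) x@grownCount)

#' @export
setGeneric("growthParams", function(x) standardGeneric("growthParams"))
#' @export
setMethod("growthParams", "SkinMask", function(x) x@params)

## ---- show methods ------------------------------------------------------

setMethod("show", "Mammogram", function(object) {
  d <- dim(object@pixels)
  cat(sprintf(
    "Mammogram %dx%d [%s %s] bitDepth=%d patient='%s' (acquired %dx%d)\n",
    d[1], d[2], object@laterality, object@projection, object@sourceBitDepth,
    object@patientID, object@originalShape[1], object@originalShape[2]
  ))
})

setMethod("show", "BreastMask", function(object) {
  cat(sprintf(
    "BreastMask %dx%d area=%d centroid=(%.1f, %.1f) orientedRight=%s\n",
    nrow(object@mask), ncol(object@mask), object@area,
    object@centroid[1], object@centroid[2], object@orientedRight
  ))
})

setMethod("show", "RadialSignature", function(object) {
  cat(sprintf(
    "RadialSignature: %d angles in [0, pi], %s, centroid=(%.1f, %.1f)\n",
    length(object@angles),
    if (object@normalized) "normalized" else "pixel distances",
    object@centroid[1], object@centroid[2]
  ))
})

setMethod("show", "DtwResult", function(object) {
  cat(sprintf(
    "DtwResult: %dx%d alignment, path length %d, index %.4g\n",
    nrow(object@cost), ncol(object@cost), nrow(object@path), object@index
  ))
})

setMethod("show", "GrowthParams", function(object) {
  cat(sprintf(
    "GrowthParams: kernel %dx%d, depth %g px, intensity window (%g, %g)\n",
    object@erosionKernel, object@erosionKernel, object@maxDepth,
    object@lowerThreshold, object@upperThreshold
  ))
})

setMethod("show", "SkinMask", function(object) {
  cat(sprintf(
    "SkinMask %dx%d: %d seeds -> %d grown pixels\n",
    nrow(object@mask), ncol(object@mask), object@seedCount,
    object@grownCount
  ))
})

setMethod("show", "PhantomSpec", function(object) {
  cat(sprintf(
    "PhantomSpec %dpx %s: axes (%g, %g), perturb %gpx x%g cycles, rim %gpx, seed %d\n",
    object@imageSize, object@laterality, object@semiAxes[1],
    object@semiAxes[2], object@perturbAmplitude, object@perturbFrequency,
    object@rimWidth, object@seed
  ))
})
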