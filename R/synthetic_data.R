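## Synthetic phantom generator: half-ellipse breasts with a sinusoidally
## perturbed boundary, a brighter skin rim, Gaussian tissue texture and
## bright annotation islands, rendered with pixel-level ground truth so
## every pipeline stage can be tested without patient data.

#' Construct a phantom specification
#'
#' Defaults render a 512 px craniocaudal-like silhouette: a near-circular
#' breast lobe anchored 130 px inside the left image edge (the chest-wall
#' side is truncated by the frame, as compression produces), with a
#' near-smooth boundary, a 6 px skin rim brighter than the interior
#' tissue, mild Gaussian texture and three annotation islands. See the
#' methods vignette for how the geometry and intensity defaults were
#' chosen.
#'
#' @param imageSize frame side in pixels.
#' @param semiAxes \code{c(a, b)}: horizontal (into the image) and
#'   vertical semi-axes in pixels.
#' @param edgeOffset lobe-center distance from the flush edge, pixels.
#' @param perturbAmplitude,perturbFrequency,perturbPhase sinusoidal
#'   boundary perturbation (pixels, cycles over \[0, pi\], radians).
#' @param rimWidth skin-rim width in pixels.
#' @param rimIntensity,interiorIntensity rim and interior intensities.
#' @param textureSd Gaussian texture standard deviation.
#' @param annotationCount number of bright annotation islands.
#' @param laterality "LEFT" or "RIGHT" (edge the breast is flush against).
#' @param seed integer RNG seed; identical specs render identically.
#' @return a \linkS4class{PhantomSpec}.
#' @export
phantomSpec <- function(imageSize = 512L, semiAxes = c(150, 150),
                        edgeOffset = 130,
                        perturbAmplitude = 1, perturbFrequency = 3,
                        perturbPhase = 0.8, rimWidth = 6,
                        rimIntensity = 0.9, interiorIntensity = 0.45,
                        textureSd = 0.03, annotationCount = 3L,
                        laterality = "LEFT", seed = 1L) {
  new("PhantomSpec",
      imageSize = as.integer(imageSize), semiAxes = as.numeric(semiAxes),
      edgeOffset = as.numeric(edgeOffset),
      perturbAmplitude = perturbAmplitude,
      perturbFrequency = perturbFrequency, perturbPhase = perturbPhase,
      rimWidth = rimWidth, rimIntensity = rimIntensity,
      interiorIntensity = interiorIntensity, textureSd = textureSd,
      annotationCount = as.integer(annotationCount),
      laterality = laterality, seed = as.integer(seed))
}

#' Render a phantom mammogram with ground truth
#'
#' Renders the breast as all pixels whose polar radius (about the
#' mid-edge anchor point) is below the perturbed elliptical boundary
#' radius; the outermost \code{rimWidth} pixels along the contour form the
#' ground-truth skin rim. Annotation islands (bright 5-15 px blocks) are
#' placed near the background corners.
#'
#' @param spec a \linkS4class{PhantomSpec}.
#' @return list with \code{mammogram} (\linkS4class{Mammogram}),
#'   \code{breastMask} (ground-truth \linkS4class{BreastMask}),
#'   \code{skinMask} (ground-truth \linkS4class{SkinMask}) and
#'   \code{spec}.
#' @export
makePhantom <- function(spec) {
  stopifnot(is(spec, "PhantomSpec"))
  validObject(spec)
  n <- spec@imageSize
  rows <- matrix(seq_len(n), n, n)
  cols <- matrix(seq_len(n), n, n, byrow = TRUE)
  c_row <- (n + 1) / 2
  ## lobe center sits edgeOffset px inside the flush edge; dx measures
  ## inward (into the image) from the center
  dx <- if (spec@laterality == "LEFT") {
    cols - (1 + spec@edgeOffset)
  } else {
    (n - spec@edgeOffset) - cols
  }
  dy <- rows - c_row
  rho <- sqrt(dx^2 + dy^2)
  phi <- atan2(dy, dx)
  a <- spec@semiAxes[1]
  b <- spec@semiAxes[2]
  r_e <- a * b / sqrt((b * cos(phi))^2 + (a * sin(phi))^2)
  u <- phi + pi / 2
  r_b <- r_e + spec@perturbAmplitude *
    sin(spec@perturbFrequency * u + spec@perturbPhase)
  breast <- rho <= r_b
  rim <- breast & rho > r_b - spec@rimWidth & spec@rimWidth > 0

  img <- withr::with_seed(spec@seed, {
    img <- matrix(0, n, n)
    tex <- matrix(stats::rnorm(n * n, 0, spec@textureSd), n, n)
    img[breast] <- spec@interiorIntensity + tex[breast]
    img[rim] <- spec@rimIntensity + tex[rim]
    ## annotation islands near the corners of the background side
    far_col <- if (spec@laterality == "LEFT") n - 30L else 10L
    anchors_r <- round(seq(20, n - 30, length.out = max(1L, spec@annotationCount)))
    for (k in seq_len(spec@annotationCount)) {
      h <- sample(2:4, 1L)
      w <- sample(2:4, 1L)
      r0 <- anchors_r[k]
      c0 <- far_col + sample(0:15, 1L)
      rr <- r0:(r0 + h - 1L)
      cc <- c0:(c0 + w - 1L)
      if (!any(breast[rr, cc])) img[rr, cc] <- 0.98
    }
    img
  })
  img[img < 0] <- 0
  img[img > 1] <- 1

  mam <- new("Mammogram",
    pixels = img, laterality = spec@laterality, projection = "CC",
    sourceBitDepth = 12L, originalShape = c(n, n),
    patientID = sprintf("PH%06d", spec@seed)
  )
  bm <- new("BreastMask",
    mask = breast, centroid = maskCentroid(breast),
    area = as.integer(sum(breast)),
    orientedRight = spec@laterality == "RIGHT"
  )
  skm <- new("SkinMask",
    mask = rim, seedCount = 0L, grownCount = as.integer(sum(rim)),
    params = growthParamsNew()
  )
  list(mammogram = mam, breastMask = bm, skinMask = skm, spec = spec)
}

#' Build a left/right phantom pair with known asymmetry labels
#'
#' The left side renders \code{base}; the right side mirrors the
#' laterality, adds \code{contourDelta} to the boundary perturbation
#' amplitude and scales the rim width by \code{rimRatio}. Labels derive
#' deterministically from the deltas: shape-asymmetric when
#' \code{contourDelta} exceeds the amplitude cutoff, skin-asymmetric when
#' \code{rimRatio} exceeds the ratio cutoff.
#'
#' @param base a \linkS4class{PhantomSpec} for the left side.
#' @param contourDelta added perturbation amplitude, pixels (>= 0).
#' @param rimRatio rim-width multiplier (>= 1).
#' @param amplitudeCutoff,ratioCutoff label cutoffs (defaults 5 px, 1.5).
#' @return list with \code{left}, \code{right} (each as returned by
#'   \code{\link{makePhantom}}), \code{labels} (logical
#'   \code{shapeAsymmetric}, \code{skinAsymmetric}) and \code{specs}.
#' @export
makePair <- function(base, contourDelta = 0, rimRatio = 1,
                     amplitudeCutoff = 5, ratioCutoff = 1.5) {
  stopifnot(rimRatio >= 1, contourDelta >= 0)
  rspec <- base
  rspec@laterality <- if (base@laterality == "LEFT") "RIGHT" else "LEFT"
  rspec@perturbAmplitude <- base@perturbAmplitude + contourDelta
  rspec@rimWidth <- base@rimWidth * rimRatio
  rspec@seed <- base@seed + 1L
  list(
    left = makePhantom(base),
    right = makePhantom(rspec),
    labels = list(
      shapeAsymmetric = contourDelta > amplitudeCutoff,
      skinAsymmetric = rimRatio > ratioCutoff
    ),
    specs = list(left = base, right = rspec)
  )
}

#' Generate a labelled phantom cohort
#'
#' Builds \code{round(n * asymFraction)} asymmetric pairs (cycled among
#' shape-only, skin-only and both) and symmetric pairs for the rest.
#' Per-pair base specs vary in boundary phase and texture seed, derived
#' deterministically from the cohort seed. Optionally writes each side as
#' 12-bit DICOM plus ground-truth PNG masks and a manifest CSV.
#'
#' @param n number of pairs (>= 1).
#' @param asymFraction fraction of asymmetric pairs in \[0, 1\].
#' @param seed cohort seed.
#' @param dir optional output directory for DICOM/PNG/manifest files.
#' @param contourDelta amplitude effect for shape-asymmetric pairs
#'   (default 40 px: a gross, radiographically evident contour
#'   deformity; see the methods vignette).
#' @param rimRatio rim-width effect for skin-asymmetric pairs
#'   (default 2.5).
#' @param base template \linkS4class{PhantomSpec}.
#' @return list of pairs (see \code{\link{makePair}}) with a
#'   \code{data.frame} manifest attached as attribute \code{"manifest"}.
#' @export
makeCohort <- function(n, asymFraction = 0.5, seed = 7L, dir = NULL,
                       contourDelta = 40, rimRatio = 2.5,
                       base = phantomSpec()) {
  stopifnot(n >= 1, asymFraction >= 0, asymFraction <= 1)
  n_asym <- round(n * asymFraction)
  kinds <- c(
    rep(c("shape", "skin", "both"), length.out = n_asym),
    rep("none", n - n_asym)
  )
  phases <- withr::with_seed(seed, stats::runif(n, 0, 2 * pi))
  pairs <- vector("list", n)
  man <- vector("list", n)
  for (i in seq_len(n)) {
    b <- base
    b@perturbPhase <- phases[i]
    b@seed <- as.integer(seed + 1000L + 7L * i)
    delta <- if (kinds[i] %in% c("shape", "both")) contourDelta else 0
    ratio <- if (kinds[i] %in% c("skin", "both")) rimRatio else 1
    pairs[[i]] <- makePair(b, contourDelta = delta, rimRatio = ratio)
    man[[i]] <- data.frame(
      pair = i, kind = kinds[i],
      contour_delta = delta, rim_ratio = ratio,
      shape_asymmetric = pairs[[i]]$labels$shapeAsymmetric,
      skin_asymmetric = pairs[[i]]$labels$skinAsymmetric
    )
  }
  manifest <- do.call(rbind, man)
  if (!is.null(dir)) {
    dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    for (i in seq_len(n)) {
      for (side in c("left", "right")) {
        ph <- pairs[[i]][[side]]
        stem <- file.path(dir, sprintf("pair%03d_%s", i, side))
        writeDicom(
          round(ph$mammogram@pixels * 4095), paste0(stem, ".dcm"),
          bitsStored = 12L,
          laterality = if (side == "left") "L" else "R",
          viewPosition = "CC", patientID = ph$mammogram@patientID
        )
        writePng(ph$breastMask@mask, paste0(stem, "_gtmask.png"))
        writePng(ph$skinMask@mask, paste0(stem, "_gtskin.png"))
      }
    }
    utils::write.csv(manifest, file.path(dir, "manifest.csv"),
                     row.names = FALSE)
  }
  attr(pairs, "manifest") <- manifest
  pairs
}
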