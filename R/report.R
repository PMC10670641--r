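## Per-patient pipeline composition and cohort-level confusion statistics:
## the machine-readable replacement for the reference system's GUI/PDF
## reporting layer.

.MAMMOASYM_VERSION <- "MammoAsym 0.1.0"

.defaultConfig <- function() {
  list(
    threshold_T = 100,
    connectivity = 8,
    angular_step = pi / 180,
    shape_threshold = 0.08,
    skin_threshold = 0.39,
    kernel = 9L,
    depth = 3,
    upper = 200,
    lower = 1
  )
}

.mergeConfig <- function(config) {
  cfg <- .defaultConfig()
  for (k in names(config)) cfg[[k]] <- config[[k]]
  cfg
}

#' Run both asymmetry analyses on an in-memory mammogram pair
#'
#' Cleans both sides, compares normalized radial signatures with DTW, and
#' compares skin thickness from the region-grown skin masks. Thickness is
#' measured per unit of breast border length (number of breast-mask
#' surface points).
#'
#' @param mLeft,mRight \linkS4class{Mammogram} objects, normalized and
#'   resized to the standard frame.
#' @param config named list overriding the default thresholds/parameters
#'   (\code{threshold_T}, \code{connectivity}, \code{angular_step},
#'   \code{shape_threshold}, \code{skin_threshold}, \code{kernel},
#'   \code{depth}, \code{upper}, \code{lower}).
#' @param patientID reported patient identifier.
#' @return an asymmetry report: named list with \code{patient_id},
#'   \code{dtw_index}, \code{shape_flag}, \code{thickness_left},
#'   \code{thickness_right}, \code{thickness_difference},
#'   \code{skin_flag}, \code{centroids}, \code{params}, \code{versions}.
#' @export
analyzePair <- function(mLeft, mRight, config = list(),
                        patientID = mLeft@patientID) {
  cfg <- .mergeConfig(config)
  params <- growthParamsNew(cfg$upper, cfg$lower, cfg$kernel, cfg$depth)

  side <- function(m) {
    cl <- cleanMammogram(m, T = cfg$threshold_T,
                         connectivity = cfg$connectivity)
    sig <- normalizeSignature(
      radialSignature(cl$mask@mask, angularStep = cfg$angular_step)
    )
    sm <- segmentSkin(cl$mammogram, cl$mask, params)
    border <- breastBorderLength(cl$mask@mask)
    list(clean = cl, sig = sig,
         thickness = skinThickness(sm, border))
  }
  L <- side(mLeft)
  R <- side(mRight)

  idx <- dtwIndex(L$sig, R$sig)
  tdiff <- thicknessDifference(L$thickness, R$thickness)
  list(
    patient_id = patientID,
    dtw_index = idx,
    shape_flag = classifyShapeAsymmetry(idx, cfg$shape_threshold),
    thickness_left = L$thickness,
    thickness_right = R$thickness,
    thickness_difference = tdiff,
    skin_flag = classifySkinAsymmetry(tdiff, cfg$skin_threshold),
    centroids = list(left = L$sig@centroid, right = R$sig@centroid),
    params = cfg,
    versions = .MAMMOASYM_VERSION
  )
}

#' Run the full pipeline on a pair of DICOM files
#'
#' read -> normalize -> resize -> clean -> shape analysis -> skin
#' analysis -> report. Deterministic for fixed inputs and config.
#'
#' @param leftPath,rightPath DICOM file paths.
#' @param config see \code{\link{analyzePair}}.
#' @param applyVoi apply VOI windowing when present.
#' @return an asymmetry report (see \code{\link{analyzePair}}).
#' @export
runPair <- function(leftPath, rightPath, config = list(), applyVoi = TRUE) {
  stage <- function(what, expr) {
    tryCatch(expr, error = function(e) {
      stop(sprintf("[%s] %s", what, conditionMessage(e)), call. = FALSE)
    })
  }
  mL <- stage("read left", readMammogram(leftPath, applyVoi))
  mR <- stage("read right", readMammogram(rightPath, applyVoi))
  mL <- stage("resize left", resizeToStandard(mL))
  mR <- stage("resize right", resizeToStandard(mR))
  stage("analyze", analyzePair(mL, mR, config,
                               patientID = mL@patientID))
}

#' Write an asymmetry report as canonical JSON
#'
#' @param report list from \code{\link{analyzePair}}/\code{\link{runPair}}.
#' @param path output JSON path.
#' @return \code{path}, invisibly.
#' @export
writeReport <- function(report, path) {
  json <- jsonlite::toJSON(report, auto_unbox = TRUE, digits = NA,
                           pretty = TRUE)
  writeLines(json, path)
  invisible(path)
}

#' Confusion statistics of predicted flags against labels
#'
#' Standard 2x2 counts and derived rates; a rate whose denominator is
#' zero is reported as NA.
#'
#' @param flags logical vector of predictions.
#' @param labels logical vector of ground-truth labels, same length.
#' @return list with \code{tp}, \code{fp}, \code{tn}, \code{fn},
#'   \code{accuracy}, \code{sensitivity}, \code{specificity}.
#' @export
confusionStats <- function(flags, labels) {
  if (length(flags) != length(labels)) {
    stop("flags and labels must have the same length")
  }
  if (length(flags) < 1L) stop("need at least one case")
  tp <- sum(flags & labels)
  fp <- sum(flags & !labels)
  tn <- sum(!flags & !labels)
  fn <- sum(!flags & labels)
  rate <- function(num, den) if (den == 0) NA_real_ else num / den
  list(
    tp = tp, fp = fp, tn = tn, fn = fn,
    accuracy = rate(tp + tn, tp + fp + tn + fn),
    sensitivity = rate(tp, tp + fn),
    specificity = rate(tn, tn + fp)
  )
}

#' Evaluate the pipeline on a labelled phantom cohort
#'
#' Runs \code{\link{analyzePair}} on every pair and scores the shape and
#' skin flags against the generator labels.
#'
#' @param cohort list of pairs from \code{\link{makeCohort}}.
#' @param config see \code{\link{analyzePair}}.
#' @return list with per-pair \code{reports}, and \code{shape} /
#'   \code{skin} confusion statistics.
#' @export
cohortEval <- function(cohort, config = list()) {
  reports <- lapply(seq_along(cohort), function(i) {
    p <- cohort[[i]]
    analyzePair(p$left$mammogram, p$right$mammogram, config,
                patientID = sprintf("pair%03d", i))
  })
  shape_flags <- vapply(reports, `[[`, logical(1), "shape_flag")
  skin_flags <- vapply(reports, `[[`, logical(1), "skin_flag")
  shape_labels <- vapply(cohort, function(p) p$labels$shapeAsymmetric,
                         logical(1))
  skin_labels <- vapply(cohort, function(p) p$labels$skinAsymmetric,
                        logical(1))
  list(
    reports = reports,
    shape = confusionStats(shape_flags, shape_labels),
    skin = confusionStats(skin_flags, skin_labels)
  )
}
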