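## Shape asymmetry: centroid-to-perimeter radial signature compared with
## dynamic time warping. Both breasts are right-oriented first, so the
## shared angular convention cancels out in the comparison. The [0, pi]
## sweep runs from straight up (theta = 0) through left (pi/2) to straight
## down (pi): for a right-oriented breast this traverses the entire
## air-skin contour, which is the perimeter the signature is meant to
## describe (a sweep anchored on the chest-wall side would waste half its
## range on the frame edge and miss the lower contour).

#' Radial signature of a breast mask
#'
#' Casts a ray from the mask centroid for each angle theta in \[0, pi\]
#' (default step one degree) and records the distance to the outermost
#' foreground pixel along the ray, so the signature is built from the
#' outermost breast pixels. Convention: theta = 0 points straight up
#' (decreasing row) and the sweep passes through left (pi/2) to straight
#' down (pi), following the air-skin contour of a right-oriented breast.
#' Rays are sampled at quarter-pixel increments on a bilinear
#' interpolation of the mask (foreground where the interpolated value is
#' at least 0.5) and the final boundary crossing is refined by bisection,
#' so distances are sub-pixel and stable under translation and scaling.
#'
#' @param mask logical matrix, nonempty, single-component.
#' @param angularStep angular step in radians (default \code{pi/180}; the
#'   coarse one-radian mode is available by passing 1).
#' @return a \linkS4class{RadialSignature}.
#' @export
radialSignature <- function(mask, angularStep = pi / 180) {
  cen <- maskCentroid(mask)
  nseg <- max(1L, as.integer(round(pi / angularStep)))
  angles <- seq(0, pi, length.out = nseg + 1L)
  nr <- nrow(mask)
  nc <- ncol(mask)
  ## a 3x3 box average of the mask gives a smoother 0.5-level set for the
  ## sub-pixel boundary estimate (symmetric, so edges are not displaced)
  num <- matrix(as.numeric(mask), nr, nc)
  pad <- matrix(0, nr + 2L, nc + 2L)
  pad[2:(nr + 1L), 2:(nc + 1L)] <- num
  num <- (pad[1:nr, 1:nc] + pad[1:nr, 2:(nc + 1L)] + pad[1:nr, 3:(nc + 2L)] +
          pad[2:(nr + 1L), 1:nc] + pad[2:(nr + 1L), 2:(nc + 1L)] +
          pad[2:(nr + 1L), 3:(nc + 2L)] +
          pad[3:(nr + 2L), 1:nc] + pad[3:(nr + 2L), 2:(nc + 1L)] +
          pad[3:(nr + 2L), 3:(nc + 2L)]) / 9
  lookup <- function(r, c) {
    ## bilinear interpolation; outside the frame counts as background
    fr <- floor(r)
    fc <- floor(c)
    wr <- r - fr
    wc <- c - fc
    val <- numeric(length(r))
    for (k in 0:3) {
      ri <- fr + k %% 2
      ci <- fc + k %/% 2
      w <- (if (k %% 2 == 0) 1 - wr else wr) *
        (if (k %/% 2 == 0) 1 - wc else wc)
      ok <- ri >= 1 & ri <= nr & ci >= 1 & ci <= nc
      val[ok] <- val[ok] + w[ok] * num[cbind(ri[ok], ci[ok])]
    }
    val
  }
  tmax <- sqrt(nr^2 + nc^2)
  tgrid <- seq(0, tmax, by = 0.25)
  distances <- vapply(angles, function(theta) {
    dr <- -cos(theta)
    dc <- -sin(theta)
    hit <- lookup(cen[1] + tgrid * dr, cen[2] + tgrid * dc) >= 0.5
    if (!any(hit)) {
      stop("signature gap: no foreground pixel along the ray at theta = ",
           signif(theta, 4))
    }
    lo <- tgrid[max(which(hit))]
    hi <- lo + 0.25
    for (it in 1:10) { # bisect the outermost 0.5-crossing
      mid <- (lo + hi) / 2
      if (lookup(cen[1] + mid * dr, cen[2] + mid * dc) >= 0.5) {
        lo <- mid
      } else {
        hi <- mid
      }
    }
    (lo + hi) / 2
  }, numeric(1))
  if (any(distances <= 0)) {
    stop("signature gap: centroid does not project onto the mask")
  }
  new("RadialSignature",
      angles = angles, distances = distances,
      normalized = FALSE, centroid = cen)
}

#' Normalize a radial signature to unit maximum
#'
#' Divides all distances by their maximum so signatures of differently
#' sized breasts are comparable and the DTW index lands in \[0, 1\].
#'
#' @param sig an unnormalized \linkS4class{RadialSignature}.
#' @return the normalized signature.
#' @export
normalizeSignature <- function(sig) {
  stopifnot(is(sig, "RadialSignature"))
  if (sig@normalized) stop("signature is already normalized")
  mx <- max(sig@distances)
  if (mx <= 0) stop("all distances must be positive")
  sig@distances <- sig@distances / mx
  sig@normalized <- TRUE
  validObject(sig)
  sig
}

#' Local DTW cost matrix
#'
#' \code{cost[i, j]} is the absolute (or squared) difference between
#' \code{dL[i]} and \code{dR[j]}.
#'
#' @param dL,dR numeric distance vectors of lengths n and m (>= 1).
#' @param metric "abs" or "squared".
#' @return n x m numeric matrix.
#' @export
dtwCostMatrix <- function(dL, dR, metric = c("abs", "squared")) {
  metric <- match.arg(metric)
  if (length(dL) < 1L || length(dR) < 1L) {
    stop("distance vectors must be nonempty")
  }
  d <- outer(dL, dR, "-")
  if (metric == "abs") abs(d) else d^2
}

#' Cumulative DTW cost under right/diagonal/down moves
#'
#' \code{cum[1,1] = cost[1,1]}; elsewhere
#' \code{cum[i,j] = cost[i,j] + min(cum[i-1,j], cum[i,j-1], cum[i-1,j-1])}
#' with out-of-range neighbours treated as +Inf, so the first row and
#' column accumulate along their only available direction.
#'
#' @param cost finite non-negative n x m matrix.
#' @return n x m cumulative cost matrix.
#' @export
dtwCumulative <- function(cost) {
  stopifnot(is.matrix(cost), all(is.finite(cost)))
  cpp_dtw_cumulative(cost)
}

#' Backtrack the optimal warping path
#'
#' From the bottom-right corner to the top-left. The path satisfies the
#' boundary, monotonicity and continuity conditions; ties are broken by
#' preferring the diagonal move, then up (i-1), then left (j-1), so
#' results are reproducible.
#'
#' @param cum cumulative cost matrix from \code{\link{dtwCumulative}}.
#' @return k x 2 integer matrix of (i, j) pairs from (1,1) to (n,m).
#' @export
dtwPath <- function(cum) {
  n <- nrow(cum)
  m <- ncol(cum)
  i <- n
  j <- m
  path <- list(c(i, j))
  while (i > 1L || j > 1L) {
    if (i > 1L && j > 1L) {
      d <- cum[i - 1L, j - 1L]
      u <- cum[i - 1L, j]
      l <- cum[i, j - 1L]
      best <- min(d, u, l)
      if (d <= best) {
        i <- i - 1L
        j <- j - 1L
      } else if (u <= best) {
        i <- i - 1L
      } else {
        j <- j - 1L
      }
    } else if (i > 1L) {
      i <- i - 1L
    } else {
      j <- j - 1L
    }
    path[[length(path) + 1L]] <- c(i, j)
  }
  out <- do.call(rbind, rev(path))
  storage.mode(out) <- "integer"
  colnames(out) <- c("i", "j")
  out
}

#' Full DTW comparison of two radial signatures
#'
#' Requires both signatures normalized and on the same angular grid.
#' The asymmetry index is the cumulative end cost divided by the warping
#' path length; with unit-bounded normalized distances every local cost is
#' at most 1, so the index lies in \[0, 1\].
#'
#' @param sigL,sigR normalized \linkS4class{RadialSignature} objects.
#' @param metric local cost metric, "abs" (default) or "squared".
#' @return a \linkS4class{DtwResult}.
#' @export
dtwCompare <- function(sigL, sigR, metric = "abs") {
  stopifnot(is(sigL, "RadialSignature"), is(sigR, "RadialSignature"))
  if (!sigL@normalized || !sigR@normalized) {
    stop("both signatures must be normalized")
  }
  if (length(sigL@angles) != length(sigR@angles) ||
      max(abs(sigL@angles - sigR@angles)) > 1e-9) {
    stop("signatures are on different angular grids")
  }
  cost <- dtwCostMatrix(sigL@distances, sigR@distances, metric)
  cum <- dtwCumulative(cost)
  path <- dtwPath(cum)
  idx <- cum[nrow(cum), ncol(cum)] / nrow(path)
  new("DtwResult", cost = cost, cumulative = cum, path = path, index = idx)
}

#' DTW asymmetry index of two normalized signatures
#'
#' @inheritParams dtwCompare
#' @return unitless index in \[0, 1\].
#' @export
dtwIndex <- function(sigL, sigR, metric = "abs") {
  dtwCompare(sigL, sigR, metric)@index
}

#' Flag shape asymmetry from the DTW index
#'
#' The flag is raised for a strictly greater index than the threshold
#' (default 0.08, the cohort-mean decision level of the reference study).
#'
#' @param index DTW asymmetry index (>= 0).
#' @param threshold decision threshold.
#' @return logical flag.
#' @export
classifyShapeAsymmetry <- function(index, threshold = 0.08) {
  stopifnot(index >= 0)
  index > threshold
}
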