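# Independent reference implementations used as oracles. Deliberately
# written with different algorithms/data structures than the package code
# they check.

# Exhaustive minimum warping-path cost: recursive enumeration over all
# monotone paths from (1,1) to (n,m) with steps (1,0), (0,1), (1,1).
enumMinPathCost <- function(cost) {
  n <- nrow(cost)
  m <- ncol(cost)
  walk <- function(i, j) {
    if (i == n && j == m) return(cost[i, j])
    branches <- c(
      if (i < n) walk(i + 1L, j),
      if (j < m) walk(i, j + 1L),
      if (i < n && j < m) walk(i + 1L, j + 1L)
    )
    cost[i, j] + min(branches)
  }
  walk(1L, 1L)
}

# Component labelling by repeated queue-based flood fill.
floodLabelOracle <- function(mask, connectivity = 8) {
  offs <- if (connectivity == 4) {
    list(c(-1, 0), c(1, 0), c(0, -1), c(0, 1))
  } else {
    list(c(-1, -1), c(-1, 0), c(-1, 1), c(0, -1),
         c(0, 1), c(1, -1), c(1, 0), c(1, 1))
  }
  lab <- matrix(0L, nrow(mask), ncol(mask))
  cur <- 0L
  for (i in seq_len(nrow(mask))) {
    for (j in seq_len(ncol(mask))) {
      if (!mask[i, j] || lab[i, j] > 0L) next
      cur <- cur + 1L
      queue <- list(c(i, j))
      lab[i, j] <- cur
      while (length(queue) > 0L) {
        p <- queue[[1]]
        queue <- queue[-1]
        for (o in offs) {
          q <- p + o
          if (q[1] < 1 || q[1] > nrow(mask) || q[2] < 1 || q[2] > ncol(mask)) next
          if (mask[q[1], q[2]] && lab[q[1], q[2]] == 0L) {
            lab[q[1], q[2]] <- cur
            queue[[length(queue) + 1L]] <- q
          }
        }
      }
    }
  }
  lab
}

# Erosion as an explicit all-neighbours-true sliding window.
erodeOracle <- function(mask, n) {
  lo <- -((n - 1) %/% 2)
  hi <- n %/% 2
  out <- matrix(FALSE, nrow(mask), ncol(mask))
  for (i in seq_len(nrow(mask))) {
    for (j in seq_len(ncol(mask))) {
      keep <- TRUE
      for (di in lo:hi) {
        for (dj in lo:hi) {
          qi <- i + di
          qj <- j + dj
          if (qi < 1 || qi > nrow(mask) || qj < 1 || qj > ncol(mask) ||
              !mask[qi, qj]) {
            keep <- FALSE
            break
          }
        }
        if (!keep) break
      }
      out[i, j] <- keep
    }
  }
  out
}

# Reference seeded region growing: FIFO frontier kept as a growing list
# with a head pointer; same acceptance rules and tie order as the
# documented contract (seeds row-major; neighbours N, NE, E, SE, S, SW,
# W, NW; visit marks at evaluation; strict thresholds; Euclidean depth
# from the chain's originating seed; seeds accepted iff not black).
growOracle <- function(img255, seeds, upper, lower, maxDepth) {
  nr <- nrow(img255)
  nc <- ncol(img255)
  seeds <- seeds[order(seeds[, 1], seeds[, 2]), , drop = FALSE]
  visited <- matrix(FALSE, nr, nc)
  inmask <- matrix(FALSE, nr, nc)
  frontier <- list()
  evaluated <- 0L
  for (s in seq_len(nrow(seeds))) {
    i <- seeds[s, 1]
    j <- seeds[s, 2]
    if (visited[i, j]) next
    visited[i, j] <- TRUE
    evaluated <- evaluated + 1L
    if (img255[i, j] > 0) {
      inmask[i, j] <- TRUE
      frontier[[length(frontier) + 1L]] <- c(i, j, seeds[s, 1], seeds[s, 2])
    }
  }
  nb <- list(c(-1, 0), c(-1, 1), c(0, 1), c(1, 1),
             c(1, 0), c(1, -1), c(0, -1), c(-1, -1))
  head <- 1L
  while (head <= length(frontier)) {
    f <- frontier[[head]]
    head <- head + 1L
    oi <- f[3]
    oj <- f[4]
    for (o in nb) {
      qi <- f[1] + o[1]
      qj <- f[2] + o[2]
      if (qi < 1 || qi > nr || qj < 1 || qj > nc) next
      if (visited[qi, qj]) next
      visited[qi, qj] <- TRUE
      evaluated <- evaluated + 1L
      v <- img255[qi, qj]
      if (v <= 0) next
      dd <- abs(v - img255[oi, oj])
      if (!((lower <= 0 || dd > lower) && dd < upper)) next
      if ((qi - oi)^2 + (qj - oj)^2 > maxDepth^2) next
      inmask[qi, qj] <- TRUE
      frontier[[length(frontier) + 1L]] <- c(qi, qj, oi, oj)
    }
  }
  list(mask = inmask, evaluated = evaluated)
}

# Surface points by per-pixel neighbour scan.
surfaceOracle <- function(mask) {
  pts <- NULL
  for (i in seq_len(nrow(mask))) {
    for (j in seq_len(ncol(mask))) {
      if (!mask[i, j]) next
      boundary <- FALSE
      for (di in -1:1) {
        for (dj in -1:1) {
          if (di == 0 && dj == 0) next
          qi <- i + di
          qj <- j + dj
          if (qi < 1 || qi > nrow(mask) || qj < 1 || qj > ncol(mask) ||
              !mask[qi, qj]) {
            boundary <- TRUE
          }
        }
      }
      if (boundary) pts <- rbind(pts, c(i, j))
    }
  }
  pts
}

# ASSD by explicit double loop over all surface point pairs.
assdOracle <- function(S1, S2) {
  P1 <- surfaceOracle(S1)
  P2 <- surfaceOracle(S2)
  dmat <- matrix(0, nrow(P1), nrow(P2))
  for (a in seq_len(nrow(P1))) {
    for (b in seq_len(nrow(P2))) {
      dmat[a, b] <- sqrt(sum((P1[a, ] - P2[b, ])^2))
    }
  }
  (sum(apply(dmat, 1, min)) + sum(apply(dmat, 2, min))) /
    (nrow(P1) + nrow(P2))
}

# Otsu threshold by brute-force scan over the 256 histogram cut points.
otsuOracle <- function(values) {
  h <- tabulate(pmin(pmax(floor(values * 256) + 1L, 1L), 256L), 256L)
  p <- h / sum(h)
  mids <- (seq_len(256) - 0.5) / 256
  best_var <- -1
  best_t <- NA_real_
  for (k in 1:255) {
    w0 <- sum(p[1:k])
    w1 <- 1 - w0
    if (w0 == 0 || w1 == 0) next
    mu0 <- sum(p[1:k] * mids[1:k]) / w0
    mu1 <- sum(p[(k + 1):256] * mids[(k + 1):256]) / w1
    v <- w0 * w1 * (mu1 - mu0)^2
    if (v > best_var) {
      best_var <- v
      best_t <- k / 256
    }
  }
  best_t
}

# Random blob mask helper for property-style tests.
randomBlob <- function(n, p = 0.5) {
  matrix(stats::runif(n * n) < p, n, n)
}

# A normalized radial signature object straight from a distance vector.
sigFrom <- function(d) {
  new("RadialSignature",
      angles = seq(0, pi, length.out = length(d)),
      distances = d / max(d), normalized = TRUE, centroid = c(0, 0))
}
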