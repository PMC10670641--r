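test_that("growth parameter validation enforces ordering and ranges", {
  p <- growthParamsNew()
  expect_equal(p@upperThreshold, 200)
  expect_equal(p@lowerThreshold, 1)
  expect_equal(p@erosionKernel, 9L)
  expect_equal(p@maxDepth, 3)
  expect_error(growthParamsNew(lowerThreshold = 250), "lowerThreshold")
  expect_error(growthParamsNew(erosionKernel = 0), "erosionKernel")
  expect_error(growthParamsNew(maxDepth = 0), "maxDepth")
})

test_that("Otsu mask separates a bimodal image and matches the scan oracle", {
  img <- matrix(c(rep(0.1, 50), rep(0.9, 50)), 10, 10)
  m <- otsuMask(img)
  expect_identical(m, img > 0.5)
  expect_error(otsuMask(matrix(0.4, 5, 5)), "degenerate")
  set.seed(44)
  for (k in 1:10) {
    img <- matrix(sample(c(rbeta(60, 2, 8), rbeta(40, 8, 2))), 10, 10)
    thr_oracle <- otsuOracle(as.numeric(img))
    m <- otsuMask(img)
    ## same binarization as the brute-force between-class-variance argmax,
    ## up to one histogram bin
    m_lo <- img > thr_oracle - 1 / 256
    m_hi <- img > thr_oracle + 1 / 256
    expect_true(all(m | !m_hi))
    expect_true(all(m_lo | !m))
  }
})

test_that("erosion shrinks squares, is identity at kernel 1, matches oracle", {
  sq <- matrix(FALSE, 14, 14)
  sq[3:12, 3:12] <- TRUE
  er <- erodeMask(sq, 3)
  expect_equal(sum(er), 64) # 10x10 -> 8x8
  expect_true(all(er[4:11, 4:11]))
  expect_identical(erodeMask(sq, 1), sq)
  set.seed(55)
  for (k in 1:8) {
    blob <- randomBlob(12, 0.7)
    for (n in c(2, 3, 5)) {
      expect_identical(erodeMask(blob, n), erodeOracle(blob, n))
    }
  }
})

test_that("border seeds are the erosion difference in row-major order", {
  sq <- matrix(FALSE, 14, 14)
  sq[3:12, 3:12] <- TRUE
  seeds <- borderSeeds(sq, erodeMask(sq, 3))
  expect_equal(nrow(seeds), 100 - 64)
  expect_true(all(diff(order(seeds[, 1], seeds[, 2])) == 1))
  expect_error(borderSeeds(sq, sq), "no seeds")
  single <- matrix(FALSE, 5, 5)
  single[3, 3] <- TRUE
  s1 <- borderSeeds(single, erodeMask(single, 3))
  expect_equal(unname(s1), matrix(c(3L, 3L), 1))
  expect_error(borderSeeds(erodeMask(sq, 3), sq), "subset")
})

test_that("padFrame adds a zero border and round-trips", {
  x <- matrix(1, 2, 2)
  p <- padFrame(x)
  expect_equal(dim(p), c(4L, 4L))
  expect_equal(sum(p), 4)
  expect_equal(p[1, ], rep(0, 4))
  expect_equal(p[2, 2], x[1, 1])
  y <- matrix(runif(30), 5, 6)
  expect_identical(padFrame(y)[2:6, 2:7], y)
})

test_that("region growth honours the black, threshold and depth conditions", {
  ## all-black image: seeds rejected by the not-black condition
  img <- matrix(0, 10, 10)
  sm <- growRegion(img, cbind(5, 5), growthParamsNew())
  expect_equal(grownCount(sm), 0L)
  ## uniform bright region: |diff| = 0 is not above the lower threshold,
  ## so nothing beyond the seeds joins
  img2 <- matrix(0.5, 10, 10)
  sm2 <- growRegion(img2, cbind(5, 5), growthParamsNew())
  expect_equal(grownCount(sm2), 1L)
  expect_true(maskArray(sm2)[5, 5])
  ## with lower threshold 0 a uniform region grows to the depth limit
  sm3 <- growRegion(img2, cbind(5, 5),
                    growthParamsNew(lowerThreshold = 0, maxDepth = 2))
  idx <- which(maskArray(sm3), arr.ind = TRUE)
  expect_true(all((idx[, 1] - 5)^2 + (idx[, 2] - 5)^2 <= 4))
  expect_gt(grownCount(sm3), 1L)
  expect_error(growRegion(img2, matrix(0L, 0, 2)), "no seeds")
})

test_that("rim phantom growth matches the independent BFS oracle", {
  ## rim of intensity 0.8 (=204) on black background, interior 0.2 (=51)
  n <- 40
  rows <- matrix(seq_len(n), n, n)
  cols <- matrix(seq_len(n), n, n, byrow = TRUE)
  rho <- sqrt((rows - 20)^2 + (cols - 20)^2)
  img <- matrix(0, n, n)
  img[rho <= 15] <- 0.2
  img[rho <= 15 & rho > 11] <- 0.8
  seeds <- which(rho <= 15 & rho > 11, arr.ind = TRUE)
  p <- growthParamsNew(upperThreshold = 200, lowerThreshold = 1,
                       maxDepth = 3)
  got <- growRegion(img, seeds, p)
  ref <- growOracle(img * 255, seeds, 200, 1, 3)
  expect_identical(maskArray(got), ref$mask)
  ## interior joins only where |204 - 51| = 153 < 200 and within depth
  expect_true(any(maskArray(got)[rho <= 11]))
  expect_false(any(maskArray(got)[img == 0]))
})

test_that("growth is pixel-identical to the oracle on random images", {
  set.seed(66)
  for (k in 1:30) {
    img <- matrix(sample(0:255, 32 * 32, replace = TRUE) / 255, 32, 32)
    img[sample(1024, 200)] <- 0
    ns <- sample(3:8, 1)
    seeds <- cbind(sample(32, ns, TRUE), sample(32, ns, TRUE))
    p <- growthParamsNew(
      upperThreshold = sample(c(50, 100, 200, 255), 1),
      lowerThreshold = sample(c(0, 1, 4, 7), 1),
      maxDepth = sample(c(3, 5, 7), 1)
    )
    got <- growRegion(img, seeds, p)
    ref <- growOracle(img * 255, seeds, p@upperThreshold,
                      p@lowerThreshold, p@maxDepth)
    expect_identical(maskArray(got), ref$mask)
  }
})

test_that("every grown pixel stays within depth of its originating seed", {
  set.seed(77)
  img <- matrix(runif(32 * 32, 0.2, 1), 32, 32)
  seeds <- cbind(sample(32, 6, TRUE), sample(32, 6, TRUE))
  seeds <- seeds[order(seeds[, 1], seeds[, 2]), , drop = FALSE]
  p <- growthParamsNew(maxDepth = 4, lowerThreshold = 0)
  res <- cpp_grow(img * 255, seeds, p@upperThreshold, p@lowerThreshold,
                  p@maxDepth)
  idx <- which(res$mask, arr.ind = TRUE)
  for (r in seq_len(nrow(idx))) {
    o <- res$origin[idx[r, 1], idx[r, 2]]
    d2 <- (idx[r, 1] - seeds[o, 1])^2 + (idx[r, 2] - seeds[o, 2])^2
    expect_lte(d2, p@maxDepth^2)
  }
  ## single-visit termination bound
  expect_lte(res$evaluated, 32 * 32)
})

test_that("growth is monotone in the depth limit", {
  set.seed(88)
  img <- matrix(runif(24 * 24, 0.1, 1), 24, 24)
  seeds <- cbind(sample(24, 4, TRUE), sample(24, 4, TRUE))
  prev <- NULL
  for (d in c(2, 3, 4, 6)) {
    cur <- maskArray(growRegion(img, seeds,
                                growthParamsNew(maxDepth = d,
                                                lowerThreshold = 0)))
    if (!is.null(prev)) expect_true(all(cur | !prev))
    prev <- cur
  }
})

test_that("segmentSkin recovers a known rim with the default parameters", {
  ## dark interior keeps the thresholded breast mask as the rim ring, so
  ## growth stays confined to the true skin
  ph <- makePhantom(phantomSpec(seed = 12L, rimWidth = 4,
                                interiorIntensity = 0.2,
                                rimIntensity = 0.85,
                                laterality = "RIGHT",
                                annotationCount = 0L))
  cl <- cleanMammogram(ph$mammogram)
  sm <- segmentSkin(cl$mammogram, cl$mask)
  gt <- maskArray(ph$skinMask)
  jac <- sum(maskArray(sm) & gt) / sum(maskArray(sm) | gt)
  expect_gte(jac, 0.7)
})

test_that("a larger erosion kernel yields at least as many seeds", {
  ph <- makePhantom(phantomSpec(seed = 13L, laterality = "RIGHT"))
  cl <- cleanMammogram(ph$mammogram)
  om <- otsuMask(pixelData(cl$mammogram), within = maskArray(cl$mask))
  s3 <- nrow(borderSeeds(om, erodeMask(om, 3)))
  s9 <- nrow(borderSeeds(om, erodeMask(om, 9)))
  expect_gte(s9, s3)
})

test_that("thickness is band area per border length", {
  band <- matrix(FALSE, 20, 110)
  band[9:11, 6:105] <- TRUE # 3 px wide along a 100 px border
  sm <- new("SkinMask", mask = band, seedCount = 100L,
            grownCount = 300L, params = growthParamsNew())
  expect_equal(skinThickness(sm, 100), 3, tolerance = 0.2)
  wide <- matrix(FALSE, 20, 110)
  wide[6:11, 6:105] <- TRUE
  sm2 <- new("SkinMask", mask = wide, seedCount = 100L,
             grownCount = 600L, params = growthParamsNew())
  expect_equal(skinThickness(sm2, 100) / skinThickness(sm, 100), 2,
               tolerance = 0.1)
  expect_error(skinThickness(sm, 0), "borderLength")
})

test_that("relative thickness difference is symmetric and strict at the flag", {
  expect_equal(thicknessDifference(2, 2), 0)
  expect_equal(thicknessDifference(2, 1), 0.5)
  expect_equal(thicknessDifference(1, 2), 0.5)
  expect_error(thicknessDifference(0, 0), "zero")
  expect_true(classifySkinAsymmetry(1.119))
  expect_false(classifySkinAsymmetry(0.0004))
  expect_false(classifySkinAsymmetry(0.39))
  expect_true(classifySkinAsymmetry(0.390001))
})
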