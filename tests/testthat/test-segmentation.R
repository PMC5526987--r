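test_that("nothing is detected on uniform background below the seed threshold", {
  f <- intensityField(matrix(5L, 40, 40))
  expect_length(detectObjects(f, thresholdConfig(minObjectArea = 1)), 0L)
})

test_that("a phantom is detected with its programmed peak as local maximum", {
  rf <- stdPhantomField(rnRadius = 15, haloScale = 20, seed = 3)
  objs <- detectObjects(rf$field, testConfig())
  expect_length(objs, 1L)
  # brute-force maximum over the object's own pixels
  expect_equal(objs[[1]]$localMax, max(pixels(rf$field)[objs[[1]]$pixels]))
  expect_equal(objs[[1]]$localMax, 255L)
  expect_equal(objs[[1]]$centroid, rf$spec@center, tolerance = 0.05)
})

test_that("well-separated blobs are two objects; touching supports are one", {
  px <- matrix(0L, 30, 30)
  px[5:9, 5:9] <- 100L
  px[20:24, 20:24] <- 150L
  cfg <- thresholdConfig(seedThreshold = 50, minObjectArea = 1,
                         borderPolicy = "keep")
  f <- intensityField(px)
  expect_length(detectObjects(f, cfg), 2L)
  # bridge the gap (diagonal chain: 8-connectivity must merge them)
  for (k in 10:19) px[k, k] <- 80L
  f2 <- intensityField(px)
  objs <- detectObjects(f2, cfg)
  expect_length(objs, 1L)
  expect_equal(objs[[1]]$localMax, 150L)
})

test_that("objects touching the border are dropped unless kept", {
  px <- matrix(0L, 30, 30)
  px[1:5, 10:14] <- 200L   # touches row 1
  px[15:19, 10:14] <- 200L
  f <- intensityField(px)
  cfgDrop <- thresholdConfig(seedThreshold = 50, minObjectArea = 1)
  cfgKeep <- thresholdConfig(seedThreshold = 50, minObjectArea = 1,
                             borderPolicy = "keep")
  expect_length(detectObjects(f, cfgDrop), 1L)
  expect_length(detectObjects(f, cfgKeep), 2L)
})

test_that("segmented disk area brackets the true disk area", {
  nr <- 120L
  px <- matrix(0L, nr, nr)
  d2 <- outer((seq_len(nr) - 60)^2, (seq_len(nr) - 60)^2, "+")
  px[d2 <= 50^2] <- 255L
  f <- intensityField(px)
  obj <- detectObjects(f, thresholdConfig(minObjectArea = 1,
                                          borderPolicy = "keep"))[[1]]
  seg <- segmentRegion(f, obj, 100)
  expect_gte(seg$area, pi * 49.5^2)
  expect_lte(seg$area, pi * 50.5^2)
  expect_equal(seg$area, diskAreaOracle(nr, nr, 60, 60, 50))
  # equal-area radius recovers the true radius to half a pixel
  expect_equal(areaToRadius(seg$area), 50, tolerance = 0.5 / 50)
  # closed comparison: threshold equal to the plateau keeps the whole disk
  expect_equal(segmentRegion(f, obj, 255)$area, diskAreaOracle(nr, nr, 60, 60, 50))
  # threshold above the object's maximum: empty region
  px2 <- px; px2[d2 <= 50^2] <- 200L
  f2 <- intensityField(px2)
  expect_equal(segmentRegion(f2, list(seed = obj$seed), 201)$area, 0L)
})

test_that("a threshold of 1 on a saturated frame selects the whole frame", {
  f <- intensityField(matrix(255L, 25, 33))
  obj <- detectObjects(f, thresholdConfig(minObjectArea = 1,
                                          borderPolicy = "keep"))[[1]]
  expect_equal(segmentRegion(f, obj, 1)$area, 25L * 33L)
})

test_that("segmentation agrees exactly with a brute-force flood fill on small fields", {
  set.seed(42)
  for (rep in 1:12) {
    nr <- sample(8:64, 1); nc <- sample(8:64, 1)
    # lumpy random field: smooth blobs plus noise
    px <- matrix(20, nr, nc)
    for (b in seq_len(sample(1:4, 1))) {
      cr <- runif(1, 1, nr); cc <- runif(1, 1, nc)
      amp <- runif(1, 60, 235); sc <- runif(1, 2, 12)
      d2 <- outer((seq_len(nr) - cr)^2, (seq_len(nc) - cc)^2, "+")
      px <- px + amp * exp(-d2 / sc^2)
    }
    px <- matrix(as.integer(pmin(255, pmax(0, round(px + rnorm(nr * nc, 0, 10))))), nr, nc)
    f <- intensityField(px)
    for (thr in sample(30:220, 3)) {
      mask <- px >= thr
      comps <- bruteComponentsOracle(mask)
      if (!length(comps)) next
      for (comp in comps) {
        # seed segmentation from this component's maximum pixel
        nrr <- nr
        v <- px[comp]
        cand <- comp[v == max(v)]
        rows <- (cand - 1L) %% nrr + 1L
        cols <- (cand - 1L) %/% nrr + 1L
        top <- rows == min(rows)
        seed <- c(min(rows), min(cols[top]))
        seg <- segmentRegion(f, list(seed = seed), thr)
        expect_identical(sort(seg$pixels), comp)
      }
    }
  }
})

test_that("area-to-radius follows the equal-area-circle convention", {
  expect_equal(areaToRadius(0), 0)
  expect_equal(areaToRadius(314), sqrt(314 / pi))
  expect_equal(areaToRadius(c(0, pi)), c(0, 1))
  expect_error(areaToRadius(-1))
})
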