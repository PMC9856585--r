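test_that("a blank channel yields an empty table, not an error", {
  img <- CalibratedImage(list(DAPI = matrix(100L, 64, 64)), umPerPx = 0.5)
  nt <- segmentNuclei(img)
  expect_identical(nrow(nucleusData(nt)), 0L)
})

test_that("two high-contrast discs segment as two nuclei of the right area", {
  img <- discImage(centers = rbind(c(40, 45), c(90, 80)),
                   radiiPx = c(8, 10))
  nt <- segmentNuclei(img)
  df <- nucleusData(nt)
  expect_identical(nrow(df), 2L)
  drawn <- sort(pi * c(8, 10)^2 * 0.5^2)
  expect_lt(max(abs(sort(df$areaUm2) - drawn) / drawn), 0.10)
})

test_that("the detected count ignores positive intensity rescaling", {
  fov <- generateFov(smallScenario(), "untreated", seed = 41,
                     channels = "DAPI")
  n1 <- nrow(nucleusData(segmentNuclei(fov$image)))
  scaled <- fov$image
  scaled@pixels$DAPI <- fov$image@pixels$DAPI * 2.5
  expect_identical(nrow(nucleusData(segmentNuclei(scaled))), n1)
})

test_that("border and minimum-area filters follow the strict-inequality rule", {
  # 24/39/40/100 px at 0.5 um/px: 6, 9.75, 10, 25 um^2
  nt <- ntFromRectangles(c(24L, 39L, 40L, 100L))
  kept <- filterNuclei(nt, minAreaUm2 = 10)
  expect_identical(nucleusData(kept)$areaUm2, c(10, 25))
  expect_identical(unname(kept@excluded[["smallArea"]]), 2L)
  # the exact-boundary nucleus (10 um^2) is retained
  expect_true(10 %in% nucleusData(kept)$areaUm2)
  # the same nucleus translated to touch the first column is excluded
  ntB <- ntFromRectangles(c(24L, 39L, 40L, 100L),
                          atBorder = c(FALSE, FALSE, TRUE, FALSE))
  ntB@nuclei$touchesBorder <- c(FALSE, FALSE, TRUE, FALSE)
  keptB <- filterNuclei(ntB, minAreaUm2 = 10)
  expect_identical(nucleusData(keptB)$areaUm2, 25)
  expect_identical(unname(keptB@excluded[["border"]]), 1L)
  # idempotent; retained rows unchanged
  again <- filterNuclei(kept, minAreaUm2 = 10)
  expect_identical(nucleusData(again), nucleusData(kept))
  # empty in, empty out
  empty <- filterNuclei(segmentNuclei(
    CalibratedImage(list(DAPI = matrix(0L, 16, 16)), umPerPx = 0.5)))
  expect_identical(nrow(nucleusData(empty)), 0L)
})

test_that("segmentation recovers the generated nuclei on a default field", {
  sc <- sliceScenario()
  fov <- generateFov(sc, "untreated", seed = 51, channels = "DAPI")
  pred <- filterNuclei(segmentNuclei(fov$image))
  truthNt <- filterNuclei(nucleusTableFromTruth(fov$truth, fov$image))
  m <- matchNuclei(pred, labelImage(truthNt), iouThreshold = 0.5)
  expect_gte(m$f1, 0.9)
})

test_that("border pixels mark nuclei as border-touching", {
  img <- discImage(centers = rbind(c(5, 64), c(64, 64)),
                   radiiPx = c(8, 8))
  nt <- segmentNuclei(img)
  df <- nucleusData(nt)
  expect_identical(sort(df$touchesBorder), c(FALSE, TRUE))
})

test_that("an image without spots yields no foci", {
  img <- discImage(centers = rbind(c(64, 64)), radiiPx = c(20),
                   fg = 2500L, bg = 500L)
  nt <- segmentNuclei(img)
  f <- detectFoci(img, "DAPI", nt)
  expect_identical(nrow(f), 0L)
})

test_that("seven rendered spots are each found and sized within 25%", {
  # camera pedestal keeps the Gaussian noise unclipped at SNR = 5
  img <- discImage(centers = rbind(c(64, 64)), radiiPx = c(28),
                   fg = 14000L, bg = 12000L)
  centers <- rbind(c(50, 50), c(78, 50), c(50, 78), c(78, 78),
                   c(64, 64), c(44, 64), c(84, 64))
  img2 <- addSpots(img, "DAPI", centers, areaUm2 = 2, amp = 20000)
  # Gaussian read noise at amp/SNR with SNR >= 5
  set.seed(7)
  noisy <- img2
  noisy@pixels$DAPI <- matrix(as.integer(pmax(0, pmin(65535,
    img2@pixels$DAPI + rnorm(128 * 128, 0, 20000 / 5)))), 128, 128)
  lab <- matrix(0L, 128, 128)
  d2 <- outer((1:128 - 64)^2, (1:128 - 64)^2, `+`)
  lab[d2 <= 28^2] <- 1L
  nt <- new("NucleusTable", labelImage = lab,
            nuclei = data.frame(label = 1L, areaPx = sum(lab),
                                areaUm2 = sum(lab) * 0.25, cx = 64,
                                cy = 64, touchesBorder = FALSE),
            umPerPx = 0.5, excluded = c(border = 0L, smallArea = 0L))
  f <- detectFoci(noisy, "DAPI", nt)
  expect_identical(nrow(f), 7L)
  expect_true(all(abs(f$areaUm2 - 2) / 2 < 0.25))
})

test_that("spots outside every nucleus are not reported", {
  img <- discImage(centers = rbind(c(40, 64)), radiiPx = c(15),
                   fg = 2500L, bg = 300L)
  img <- addSpots(img, "DAPI", rbind(c(100, 64)), areaUm2 = 2,
                  amp = 20000)
  lab <- matrix(0L, 128, 128)
  d2 <- outer((1:128 - 64)^2, (1:128 - 40)^2, `+`)
  lab[d2 <= 15^2] <- 1L
  nt <- new("NucleusTable", labelImage = lab,
            nuclei = data.frame(label = 1L, areaPx = sum(lab),
                                areaUm2 = sum(lab) * 0.25, cx = 40,
                                cy = 64, touchesBorder = FALSE),
            umPerPx = 0.5, excluded = c(border = 0L, smallArea = 0L))
  f <- detectFoci(img, "DAPI", nt)
  expect_identical(nrow(f), 0L)
  expect_identical(attr(f, "outsideCount"), 1L)
})

test_that("a z-stack focus channel must be projected before detection", {
  fov <- generateFov(smallScenario(), "untreated", seed = 61,
                     channels = c("DAPI", "53BP1"))
  nt <- filterNuclei(segmentNuclei(fov$image))
  expect_error(detectFoci(fov$image, "53BP1", nt), "maxProject")
})

test_that("noiseless well-separated spots are counted exactly", {
  sc <- noiselessScenario(widthPx = 320L, heightPx = 320L, nNuclei = 40L,
                          fociLambda = 2, rad51Lambda = 0)
  fov <- generateFov(sc, "untreated", seed = 71,
                     channels = c("DAPI", "53BP1"))
  img <- fov$image
  img@pixels$`53BP1` <- maxProject(getChannel(img, "53BP1"))
  nt <- filterNuclei(nucleusTableFromTruth(fov$truth, img))
  f <- detectFoci(img, "53BP1", nt)
  labs <- nucleusData(nt)$label
  det <- countsPerNucleus(f, labs)
  truthN <- truthCountsFor(fov$truth, labs)
  # restrict to nuclei whose spots are pairwise separated by > 4 px
  sep <- vapply(labs, function(l) {
    s <- fov$truth@foci[fov$truth@foci$label == l, ]
    if (nrow(s) < 2) return(TRUE)
    d <- as.matrix(dist(cbind(s$cx, s$cy))); diag(d) <- Inf
    min(d) > 4
  }, logical(1))
  expect_gt(sum(sep), 20)
  expect_identical(det[sep], truthN[sep])
})
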