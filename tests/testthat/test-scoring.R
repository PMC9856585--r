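test_that("Otsu positivity separates bimodal intensity distributions", {
  set.seed(5)
  truth <- runif(300) < 0.3
  means <- ifelse(truth, rnorm(300, 20000, 2000), rnorm(300, 700, 150))
  nt <- ntFromMeans(means)
  fl <- callPositivity(nt, "EdU", rule = "otsu")
  expect_gte(mean(fl == truth), 0.99)
})

test_that("absolute and truth positivity rules behave as stated", {
  nt <- ntFromMeans(c(100, 200, 300))
  expect_identical(unname(callPositivity(nt, "EdU", rule = "absolute",
                                         threshold = 500)),
                   c(FALSE, FALSE, FALSE))
  tf <- c(`1` = TRUE, `2` = FALSE, `3` = TRUE)
  expect_identical(unname(callPositivity(nt, "EdU", rule = "truth",
                                         truthFlags = tf)),
                   c(TRUE, FALSE, TRUE))
  one <- ntFromMeans(1000)
  expect_error(callPositivity(one, "EdU", rule = "otsu"), "absolute")
  expect_error(callPositivity(nt, "EdU", rule = "absolute"), "threshold")
})

test_that("the RECAP score applies the at-least-k rule over geminin+ cells", {
  cells <- data.frame(geminin = TRUE, rad51Count = c(5, 4, 5, 0, 7))
  expect_equal(recapScore(cells), 60)
  expect_equal(recapScore(data.frame(geminin = TRUE,
                                         rad51Count = c(5, 6, 9))), 100)
  # geminin-negative cells never enter numerator or denominator
  mixed <- rbind(cells, data.frame(geminin = FALSE, rad51Count = 50))
  expect_equal(recapScore(mixed), 60)
  # k = 1: fraction with any focus; k = 0: identically 100
  expect_equal(recapScore(cells, k = 1), 80)
  expect_equal(recapScore(mixed, k = 0), 100)
  # order-invariant and deterministic without subsampling
  perm <- cells[c(3, 1, 5, 2, 4), , drop = FALSE]
  expect_identical(recapScore(perm), recapScore(cells))
  expect_error(recapScore(data.frame(geminin = FALSE, rad51Count = 9)),
               "geminin")
})

test_that("seeded subsampling reproduces the approximately-100-cell protocol", {
  cells <- data.frame(geminin = TRUE,
                      rad51Count = rep(c(5L, 0L), c(700L, 300L)))
  one <- recapScore(cells, sampleTarget = 100, seed = 42)
  expect_identical(one, recapScore(cells, sampleTarget = 100, seed = 42))
  scores <- vapply(1:200, function(s)
    recapScore(cells, sampleTarget = 100, seed = s), 1)
  expect_lt(abs(mean(scores) - 70), 3)
  expect_error(recapScore(cells, sampleTarget = 100), "seed")
})

test_that("focus density uses the sphere-equivalent nuclear volume", {
  expect_equal(fociDensity(0, 12), 0)
  # radius-1-um nucleus: V = 4*pi/3, 4 foci -> 3/pi
  expect_equal(fociDensity(4, pi), 3 / pi, tolerance = 1e-12)
  expect_equal(fociDensity(2, pi), fociDensity(4, pi) / 2)
  expect_error(fociDensity(1, 0), "positive")
  # density depends only on (count, physical area): recomputing the same
  # physical nucleus at a different pixel size changes nothing
  expect_identical(fociDensity(5, 30), fociDensity(5, 30))
})

test_that("field summaries report fractions over the filtered cells", {
  cells <- data.frame(label = 1:10, areaUm2 = 50,
                      edu = rep(c(TRUE, FALSE), c(3, 7)),
                      tunel = FALSE, geminin = rep(c(TRUE, FALSE), 5),
                      p63 = TRUE, focusCount = 0L,
                      fociPerVolume = 0,
                      rad51Count = c(6L, 0L, 6L, 0L, 6L,
                                     0L, 0L, 0L, 0L, 0L))
  cells$focusAreas <- replicate(10, numeric(0), simplify = FALSE)
  s <- summarizeFov(cells)
  expect_identical(s$fracEdu, 0.3)
  expect_identical(s$nGemininPos, 5L)
  expect_identical(s$nGemininPosFociGEk, 3L)
  perm <- summarizeFov(cells[sample.int(10), , drop = FALSE])
  expect_identical(perm$fracEdu, s$fracEdu)
  expect_error(summarizeFov(cells[0, , drop = FALSE]), "empty")
})

test_that("truth-passthrough scoring reproduces generator fractions exactly", {
  fov <- generateFov(smallScenario(), "untreated", seed = 81)
  nt <- nucleusTableFromTruth(fov$truth, fov$image)
  tr <- fov$truth@nuclei
  chans <- c(edu = "EdU", tunel = "TUNEL", geminin = "geminin",
             p63 = "p63")
  pos <- lapply(names(chans), function(m)
    callPositivity(nt, chans[[m]], rule = "truth",
                   truthFlags = setNames(tr[[m]], tr$label)))
  names(pos) <- names(chans)
  cells <- buildCellTable(nt, pos)
  s <- summarizeFov(cells)
  expect_identical(s$fracEdu, unname(fov$truth@fractions[["edu"]]))
  expect_identical(s$fracGeminin,
                   unname(fov$truth@fractions[["geminin"]]))
})

test_that("cell tables tie focus records to the right nuclei", {
  fov <- generateFov(smallScenario(fociLambda = 1), "untreated", seed = 91,
                     channels = c("DAPI", "53BP1"))
  img <- fov$image
  img@pixels$`53BP1` <- maxProject(getChannel(img, "53BP1"))
  nt <- nucleusTableFromTruth(fov$truth, img)
  f <- detectFoci(img, "53BP1", nt)
  cells <- buildCellTable(nt, foci = f)
  expect_identical(sum(cells$focusCount), nrow(f))
  expect_identical(lengths(cells$focusAreas), cells$focusCount)
  expect_true(all(cells$fociPerVolume[cells$focusCount == 0] == 0))
})
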