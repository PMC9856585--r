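test_that("an empty scenario yields an empty field with undefined fractions", {
  sc <- sliceScenario(widthPx = 64L, heightPx = 64L, nNuclei = 0L)
  fov <- generateFov(sc, "untreated", seed = 1)
  expect_true(all(fov$truth@labelImage == 0L))
  expect_identical(nrow(fov$truth@nuclei), 0L)
  expect_true(all(is.na(fov$truth@fractions)))
})

test_that("degenerate probability flags every nucleus positive", {
  sc <- sliceScenario(widthPx = 160L, heightPx = 160L, nNuclei = 15L,
                      fracEdu = 1)
  fov <- generateFov(sc, "untreated", seed = 3)
  expect_true(all(fov$truth@nuclei$edu))
  expect_identical(unname(fov$truth@fractions[["edu"]]), 1)
})

test_that("generation is deterministic and leaves the caller's RNG alone", {
  sc <- smallScenario()
  set.seed(123); before <- .Random.seed
  a <- generateFov(sc, "untreated", seed = 11)
  expect_identical(.Random.seed, before)
  b <- generateFov(sc, "untreated", seed = 11)
  expect_identical(a$image@pixels, b$image@pixels)
  expect_identical(a$truth@nuclei, b$truth@nuclei)
  c <- generateFov(sc, "untreated", seed = 12)
  expect_false(identical(a$image@pixels$DAPI, c$image@pixels$DAPI))
})

test_that("fractions above one are clipped with a warning", {
  sc <- smallScenario(fracTunel = 0.5, treatmentEffect = list(
    hot = c(rp = 1, ra = 3, rf = 1)))
  expect_warning(fov <- generateFov(sc, "hot", seed = 5), "clipped")
  expect_lte(fov$truth@fractions[["tunel"]], 1)
})

test_that("truth fractions equal the recomputed mean of the truth flags", {
  fov <- generateFov(smallScenario(), "5Gy", seed = 21)
  fl <- fov$truth@nuclei
  expect_identical(unname(fov$truth@fractions),
                   c(mean(fl$edu), mean(fl$tunel), mean(fl$geminin),
                     mean(fl$p63)))
  # focus centers lie inside their nucleus mask
  fc <- fov$truth@foci
  expect_true(all(fov$truth@labelImage[cbind(fc$cy, fc$cx)] == fc$label))
})

test_that("focus counts and treatment effects follow the generator law", {
  sc <- sliceScenario(widthPx = 800L, heightPx = 800L, nNuclei = 500L)
  fov <- generateFov(sc, "untreated", seed = 31, channels = "DAPI")
  # law of large numbers: mean count within 3 standard errors of lambda
  expect_lt(abs(mean(fov$truth@nuclei$fociCount) - 4), 3 * sqrt(4 / 500))
  # proliferation multiplier orders the realized EdU fractions
  scLo <- sliceScenario(widthPx = 800L, heightPx = 800L, nNuclei = 500L,
                        treatmentEffect = list(t = c(0.3, 1, 1)))
  scHi <- sliceScenario(widthPx = 800L, heightPx = 800L, nNuclei = 500L,
                        treatmentEffect = list(t = c(0.9, 1, 1)))
  fLo <- generateFov(scLo, "t", seed = 32, channels = "DAPI")
  fHi <- generateFov(scHi, "t", seed = 33, channels = "DAPI")
  expect_lt(fLo$truth@fractions[["edu"]], fHi$truth@fractions[["edu"]])
})

test_that("placement failure reports the achieved density", {
  sc <- sliceScenario(widthPx = 64L, heightPx = 64L, nNuclei = 200L)
  expect_error(generateFov(sc, "untreated", seed = 1),
               "placement failed.*density", ignore.case = TRUE)
})

test_that("unknown conditions are rejected by name", {
  expect_error(generateFov(smallScenario(), "9Gy", seed = 1), "9Gy")
})

test_that("an experiment writes one TIFF per field plus manifest and truth", {
  dir <- withr::local_tempdir()
  res <- generateExperiment(smallScenario(),
                            data.frame(condition = c("untreated", "5Gy"),
                                       nFov = c(2L, 2L)), dir)
  mf <- read.csv(res$manifest)
  expect_identical(nrow(mf), 4L)
  expect_true(all(file.exists(file.path(dir, mf$file))))
  expect_length(list.files(dir, pattern = "\\.tif$"), 4L)
  expect_true(file.exists(res$truth))
  # refuse to clobber
  expect_error(generateExperiment(smallScenario(),
                                  data.frame(condition = "untreated",
                                             nFov = 1L), dir),
               "overwrite")
  # empty design: empty manifest, no images
  dir2 <- withr::local_tempdir()
  res2 <- generateExperiment(smallScenario(),
                             data.frame(condition = character(0),
                                        nFov = integer(0)), dir2)
  expect_identical(nrow(read.csv(res2$manifest)), 0L)
  expect_length(list.files(dir2, pattern = "\\.tif$"), 0L)
})

test_that("written fields read back identical to the in-memory arrays", {
  dir <- withr::local_tempdir()
  sc <- smallScenario()
  res <- generateExperiment(sc, data.frame(condition = "untreated",
                                           nFov = 1L), dir)
  mf <- read.csv(res$manifest, check.names = FALSE)
  img <- readCalibratedImage(file.path(dir, mf$file[1]), mf[1, ])
  mem <- generateFov(sc, "untreated", seed = sc@seed + 1L)
  expect_identical(img@pixels, mem$image@pixels)
  expect_identical(pixelSize(img), sc@umPerPx)
})
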