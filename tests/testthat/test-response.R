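test_that("sample aggregation reports mean and SEM per condition", {
  fov <- data.frame(sampleId = "S1",
                    condition = rep(c("untreated", "5Gy"), c(3, 1)),
                    fracEdu = c(0.30, 0.32, 0.28, 0.10),
                    fracTunel = c(0.04, 0.05, 0.03, 0.08),
                    fracGeminin = 0.3, fracP63 = 0.9)
  s <- summarizeSample(fov)
  un <- s[s$condition == "untreated", ]
  expect_equal(un$meanFracEdu, 0.30)
  expect_equal(un$semFracEdu, sd(c(0.30, 0.32, 0.28)) / sqrt(3))
  # SEM undefined with a single field
  expect_true(is.na(s[s$condition == "5Gy", "semFracEdu"]))
})

test_that("relative proliferation and apoptosis ratio follow their ratios", {
  expect_equal(relativeProliferation(0.06, 0.12), 50)
  expect_equal(relativeProliferation(0.12, 0.12), 100)
  expect_error(relativeProliferation(0.1, 0), "control")
  expect_equal(apoptosisRatio(0.08, 0.04), 2)
  expect_equal(apoptosisRatio(0.04, 0.04), 1)
  expect_error(apoptosisRatio(0.1, 0), "control")
})

test_that("the sensitivity classifier switches exactly at its boundaries", {
  expect_identical(as.character(classifyIrResponse(25)), "sensitive")
  expect_identical(as.character(classifyIrResponse(45)), "intermediate")
  expect_identical(as.character(classifyIrResponse(75)), "resistant")
  # scan a fine grid and read off the switch points
  grid <- seq(0, 100, by = 0.1)
  cls <- classifyIrResponse(grid)
  expect_equal(max(grid[cls == "sensitive"]), 29.9)
  expect_equal(min(grid[cls == "intermediate"]), 30)
  expect_equal(max(grid[cls == "intermediate"]), 59.9)
  expect_equal(min(grid[cls == "resistant"]), 60)
  # total and monotone
  expect_false(anyNA(cls))
  expect_true(all(diff(as.integer(cls)) >= 0))
  expect_error(classifyIrResponse(-1), "nonnegative")
  expect_identical(as.character(classifyIrResponse(20, 25, 80)),
                   "sensitive")
})

test_that("the HR-proficiency call is strict at 50 percent", {
  expect_true(hrCall(51))
  expect_false(hrCall(50))
  expect_false(hrCall(0))
  expect_true(hrCall(100))
  expect_error(hrCall(101), "0, 100")
  expect_error(hrCall(-2), "0, 100")
})

test_that("the Student t comparison matches a hand-computed oracle", {
  a <- c(0.1, 0.2, 0.3); b <- c(0.4, 0.5, 0.6)
  res <- compareFractions(a, b)
  # independent closed-form pooled-variance oracle
  sp2 <- (sum((a - mean(a))^2) + sum((b - mean(b))^2)) /
    (length(a) + length(b) - 2)
  tOracle <- (mean(a) - mean(b)) /
    sqrt(sp2 * (1 / length(a) + 1 / length(b)))
  pOracle <- 2 * pt(-abs(tOracle), df = length(a) + length(b) - 2)
  expect_equal(res$statistic, tOracle, tolerance = 1e-10)
  expect_equal(res$p.value, pOracle, tolerance = 1e-10)
  expect_equal(res$df, 4)
  # identical groups: t = 0, p = 1; order invariance
  same <- compareFractions(c(1, 2, 3), c(3, 2, 1))
  expect_equal(same$statistic, 0)
  expect_equal(same$p.value, 1)
  expect_error(compareFractions(1, c(1, 2)), "at least 2")
})

test_that("the Kruskal-Wallis comparison matches a brute-force rank oracle", {
  set.seed(77)
  g <- list(round(rnorm(10, 0, 1), 1), round(rnorm(10, 0.5, 1), 1),
            round(rnorm(10, 1, 1), 1))   # rounding forces ties
  res <- compareFoci(g)
  values <- unlist(g); N <- length(values)
  r <- rank(values)
  splits <- split(r, rep(seq_along(g), lengths(g)))
  hRaw <- 12 / (N * (N + 1)) *
    sum(vapply(splits, function(x) length(x) * (mean(x) - (N + 1) / 2)^2,
               1))
  ties <- table(values)
  hOracle <- hRaw / (1 - sum(ties^3 - ties) / (N^3 - N))
  pOracle <- pchisq(hOracle, df = 2, lower.tail = FALSE)
  expect_equal(res$statistic, hOracle, tolerance = 1e-10)
  expect_equal(res$p.value, pOracle, tolerance = 1e-10)
  # identical groups: H = 0, p = 1
  same <- compareFoci(list(c(1, 2, 3), c(1, 2, 3)))
  expect_equal(same$statistic, 0)
  expect_equal(same$p.value, 1)
  # invariant under strictly monotone transforms
  tr <- compareFoci(lapply(g, function(x) exp(x)))
  expect_equal(tr$statistic, res$statistic, tolerance = 1e-12)
  expect_error(compareFoci(list(numeric(0), 1:3)), "nonempty")
  expect_error(compareFoci(list(1:3)), "two groups")
})

test_that("generator effect parameters are recovered through scoring", {
  sc <- sliceScenario(widthPx = 640L, heightPx = 640L, nNuclei = 320L,
                      treatmentEffect = list(
                        untreated = c(rp = 1, ra = 1, rf = 1),
                        treated = c(rp = 0.25, ra = 2, rf = 1)))
  frac <- function(cond, seed) {
    fov <- generateFov(sc, cond, seed,
                       channels = c("DAPI", "EdU", "TUNEL"))
    nt <- filterNuclei(segmentNuclei(fov$image))
    c(edu = mean(callPositivity(nt, "EdU", rule = "otsu")),
      tunel = mean(callPositivity(nt, "TUNEL", rule = "otsu")),
      eduT = fov$truth@fractions[["edu"]],
      tunelT = fov$truth@fractions[["tunel"]])
  }
  tr <- (frac("treated", 101) + frac("treated", 102)) / 2
  un <- (frac("untreated", 103) + frac("untreated", 104)) / 2
  # parameter recovery: relative proliferation tracks rp = 0.25
  rel <- relativeProliferation(tr[["edu"]], un[["edu"]])
  expect_lt(abs(rel - 25), 10)
  # the measured apoptosis ratio matches the ratio realized in the truth
  # flags (the truth ratio itself scatters around ra = 2 at this n, so the
  # tight comparison is measurement vs realized truth)
  ratio <- apoptosisRatio(tr[["tunel"]], un[["tunel"]])
  truthRatio <- tr[["tunelT"]] / un[["tunelT"]]
  expect_lt(abs(ratio - truthRatio), 0.3)
  expect_gt(ratio, 1.2)
})
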