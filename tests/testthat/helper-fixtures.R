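# Shared fixture builders. Everything is generated in code at test time;
# no binary fixtures are stored.

# a fast, small scenario for tests that only need plumbing to work
smallScenario <- function(...) {
  sliceScenario(widthPx = 192L, heightPx = 192L, nNuclei = 25L,
                seed = 99L, ...)
}

# scenario with the camera switched off (no shot/read noise, flat background)
noiselessScenario <- function(...) {
  sliceScenario(noise = c(gain = 0, readSd = 0, backgroundAmplitude = 0),
                ...)
}

# NucleusTable carrying prescribed per-nucleus mean intensities
ntFromMeans <- function(means, channel = "EdU", umPerPx = 0.5,
                        areaPx = 100L) {
  n <- length(means)
  df <- data.frame(label = seq_len(n), areaPx = areaPx,
                   areaUm2 = areaPx * umPerPx^2,
                   cx = seq_len(n), cy = seq_len(n),
                   touchesBorder = FALSE)
  df[[paste0("mean_", channel)]] <- as.numeric(means)
  new("NucleusTable", labelImage = matrix(0L, 2, 2), nuclei = df,
      umPerPx = umPerPx, excluded = c(border = 0L, smallArea = 0L))
}

# NucleusTable whose label image holds one rectangle per nucleus, with
# areas (in px) and border contact under the caller's control
ntFromRectangles <- function(areasPx, umPerPx = 0.5, atBorder = NULL,
                             size = 128L) {
  n <- length(areasPx)
  if (is.null(atBorder)) atBorder <- rep(FALSE, n)
  lab <- matrix(0L, size, size)
  x0 <- 3L
  for (k in seq_len(n)) {
    wk <- ceiling(sqrt(areasPx[k]))
    hk <- ceiling(areasPx[k] / wk)
    npx <- 0L
    r0 <- if (atBorder[k]) 1L else 10L
    for (c in x0:(x0 + wk - 1L)) for (r in r0:(r0 + hk - 1L)) {
      if (npx >= areasPx[k]) break
      lab[r, c] <- k
      npx <- npx + 1L
    }
    x0 <- x0 + wk + 3L
  }
  idx <- which(lab > 0L)
  labv <- lab[idx]
  areaPx <- tabulate(labv, n)
  stopifnot(identical(areaPx, as.integer(areasPx)))
  df <- data.frame(label = seq_len(n), areaPx = areaPx,
                   areaUm2 = areaPx * umPerPx^2,
                   cx = as.numeric(rowsum(((idx - 1L) %/% size) + 1,
                                          labv) / areaPx),
                   cy = as.numeric(rowsum(((idx - 1L) %% size) + 1,
                                          labv) / areaPx),
                   touchesBorder = atBorder)
  new("NucleusTable", labelImage = lab, nuclei = df, umPerPx = umPerPx,
      excluded = c(border = 0L, smallArea = 0L))
}

# image holding filled bright discs on a dim background
discImage <- function(centers, radiiPx, size = 128L, fg = 30000L,
                      bg = 500L, umPerPx = 0.5, channel = "DAPI") {
  m <- matrix(bg, size, size)
  for (i in seq_len(nrow(centers))) {
    d2 <- outer((seq_len(size) - centers[i, 2])^2,
                (seq_len(size) - centers[i, 1])^2, `+`)
    m[d2 <= radiiPx[i]^2] <- fg
  }
  storage.mode(m) <- "integer"
  px <- list(); px[[channel]] <- m
  CalibratedImage(px, umPerPx = umPerPx)
}

# add Gaussian spots of a given true half-maximum area to a channel
addSpots <- function(image, channel, centers, areaUm2, amp = 20000) {
  m <- as.numeric(getChannel(image, channel))
  dim(m) <- dim(getChannel(image, channel))
  sigma <- sqrt((areaUm2 / image@umPerPx^2) / (2 * pi * log(2)))
  size <- nrow(m)
  for (i in seq_len(nrow(centers))) {
    d2 <- outer((seq_len(size) - centers[i, 2])^2,
                (seq_len(size) - centers[i, 1])^2, `+`)
    m <- m + amp * exp(-d2 / (2 * sigma^2))
  }
  m <- matrix(as.integer(pmin(65535, round(m))), size, size)
  image@pixels[[channel]] <- m
  image
}

# per-nucleus detected focus counts aligned with a label vector
countsPerNucleus <- function(foci, labels) {
  tabulate(factor(foci$nucleusLabel, levels = labels),
           nbins = length(labels))
}

# truth focus counts for the retained labels of a (possibly filtered) table
truthCountsFor <- function(truth, labels, column = "fociCount") {
  truth@nuclei[[column]][match(labels, truth@nuclei$label)]
}
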