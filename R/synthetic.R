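# Synthetic tumor-slice FoV generator with ground truth.
#
# Emulates the statistical structure the downstream assays assume: elliptical
# nuclei with mildly perturbed boundaries, per-cell marker positivity drawn
# from condition-scaled fractions, Poisson focus counts with log-normal
# half-maximum focus areas, Poisson-Gaussian camera noise and a low-order
# polynomial background. It does not emulate tissue architecture.

# run expr with a private RNG stream; global .Random.seed is restored
withLocalSeed <- function(seed, expr) {
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

# intensity means (16-bit counts) of the rendered structures
.render <- list(
  baseBackground = 800,
  dapiNucleus    = c(mean = 15000, sd = 1500),
  markerPos      = c(mean = 20000, sd = 2000),
  markerNeg      = c(mean = 700,  sd = 100),
  p63Pos         = c(mean = 12000, sd = 1500),
  panNuclear     = c(mean = 2500, sd = 300),   # 53BP1/RAD51 diffuse signal
  focusAmp       = c(mean = 25000, sd = 2000),
  boundaryAmp    = 0.06,                        # radial perturbation of nuclei
  zSigma         = 0.45                         # focus spread across planes
)

# place non-overlapping perturbed ellipses by rejection sampling
placeNuclei <- function(w, h, n, radiusUm, umPerPx, attemptBound) {
  rMeanPx <- radiusUm[1] / umPerPx
  out <- data.frame(cx = numeric(0), cy = numeric(0), a = numeric(0),
                    b = numeric(0), theta = numeric(0), phase = numeric(0),
                    radiusUm = numeric(0))
  if (n == 0L) return(out)
  bound <- numeric(n)
  attempts <- 0L
  placed <- 0L
  amp <- .render$boundaryAmp
  while (placed < n) {
    if (attempts >= attemptBound) {
      areaMm2 <- w * h * umPerPx^2 / 1e6
      stop(sprintf(paste0("nucleus placement failed after %d attempts: ",
                          "placed %d of %d nuclei (achieved density %.0f ",
                          "nuclei/mm^2); reduce nNuclei or enlarge the field"),
                   attempts, placed, n, placed / areaMm2))
    }
    attempts <- attempts + 1L
    rUm <- max(1.5, stats::rnorm(1, radiusUm[1], radiusUm[2]))
    rPx <- rUm / umPerPx
    u <- stats::runif(1, 1, 1.3)
    a <- rPx * sqrt(u); b <- rPx / sqrt(u)
    cx <- stats::runif(1, 1, w); cy <- stats::runif(1, 1, h)
    rb <- max(a, b) * (1 + amp) + 1
    if (placed > 0L) {
      d2 <- (out$cx - cx)^2 + (out$cy - cy)^2
      if (any(d2 < (rb + bound[seq_len(placed)])^2)) next
    }
    placed <- placed + 1L
    bound[placed] <- rb
    out[placed, ] <- list(cx, cy, a, b, stats::runif(1, 0, pi),
                          stats::runif(1, 0, 2 * pi), rUm)
  }
  out
}

# rasterise one perturbed ellipse into the label image (in place semantics)
rasteriseNucleus <- function(lab, k, p) {
  h <- nrow(lab); w <- ncol(lab)
  amp <- .render$boundaryAmp
  rmax <- max(p$a, p$b) * (1 + amp) + 1
  rows <- max(1L, floor(p$cy - rmax)):min(h, ceiling(p$cy + rmax))
  cols <- max(1L, floor(p$cx - rmax)):min(w, ceiling(p$cx + rmax))
  dy <- rep(rows - p$cy, times = length(cols))
  dx <- rep(cols - p$cx, each = length(rows))
  xr <- dx * cos(p$theta) + dy * sin(p$theta)
  yr <- -dx * sin(p$theta) + dy * cos(p$theta)
  nx <- xr / p$a; ny <- yr / p$b
  rho <- sqrt(nx^2 + ny^2)
  ang <- atan2(ny, nx)
  inside <- rho <= 1 + amp * sin(3 * ang + p$phase)
  sub <- lab[rows, cols]
  sel <- inside & sub == 0L
  sub[sel] <- k
  lab[rows, cols] <- sub
  lab
}

# sample focus centers on mask pixels, preferring pairwise separation minSep
sampleFocusCenters <- function(maskIdx, m, minSep, h) {
  if (m == 0L || length(maskIdx) == 0L)
    return(data.frame(cx = integer(0), cy = integer(0)))
  ys <- ((maskIdx - 1L) %% h) + 1L
  xs <- ((maskIdx - 1L) %/% h) + 1L
  cx <- integer(m); cy <- integer(m)
  for (i in seq_len(m)) {
    ok <- FALSE
    for (try in 1:60) {
      j <- sample.int(length(maskIdx), 1L)
      if (i == 1L ||
          all((xs[j] - cx[seq_len(i - 1L)])^2 +
              (ys[j] - cy[seq_len(i - 1L)])^2 >= minSep^2)) {
        ok <- TRUE; break
      }
    }
    # dense nuclei: accept the last draw; merged blobs count once downstream
    cx[i] <- xs[j]; cy[i] <- ys[j]
  }
  data.frame(cx = cx, cy = cy)
}

# add 2D Gaussian spots in one pass; the true half-maximum area of each
# spot is pi * (sigma*sqrt(2 ln 2))^2
renderSpots <- function(img, cx, cy, sigmaPx, amp) {
  if (length(cx) == 0L) return(img)
  h <- nrow(img); w <- ncol(img)
  idxList <- vector("list", length(cx))
  valList <- vector("list", length(cx))
  for (i in seq_along(cx)) {
    r <- ceiling(4 * sigmaPx[i])
    rows <- max(1L, cy[i] - r):min(h, cy[i] + r)
    cols <- max(1L, cx[i] - r):min(w, cx[i] + r)
    dy <- rep(rows - cy[i], times = length(cols))
    dx <- rep(cols - cx[i], each = length(rows))
    idxList[[i]] <- rep((cols - 1L) * h, each = length(rows)) + rows
    valList[[i]] <- amp[i] * exp(-(dx^2 + dy^2) / (2 * sigmaPx[i]^2))
  }
  idx <- unlist(idxList); val <- unlist(valList)
  add <- rowsum(val, idx)
  at <- as.integer(rownames(add))
  img[at] <- img[at] + add[, 1]
  img
}

# Poisson shot noise (with camera gain) + Gaussian read noise, 16-bit clamp
applyCameraNoise <- function(signal, noise) {
  gain <- noise[["gain"]]
  n <- length(signal)
  x <- if (gain > 0) stats::rpois(n, signal / gain) * gain else signal
  x <- x + stats::rnorm(n, 0, noise[["readSd"]])
  m <- matrix(as.integer(pmin(65535, pmax(0, round(x)))),
              nrow = nrow(signal))
  m
}

#' Generate one synthetic field of view with ground truth
#'
#' Draws a field of non-overlapping nuclei, assigns per-cell truth flags at
#' the condition-scaled positive fractions (EdU scaled by `rp`, TUNEL by
#' `ra`, both clipped to 1 with a warning), draws per-nucleus 53BP1 focus
#' counts from `Poisson(fociLambda * rf)` and RAD51 counts from
#' `Poisson(rad51Lambda)`, renders all channels with camera noise, and
#' returns the image together with the exact generator truth. The 53BP1
#' channel is emitted as a 3-plane z-stack (1 um step, planes bottom to top)
#' so the analysis side must maximum-project it.
#'
#' Identical `(scenario, condition, seed)` triples reproduce identical
#' output bit for bit; the caller's RNG state is left untouched.
#'
#' @param scenario a [SliceScenario-class].
#' @param condition a condition id present in `scenario`'s treatment map.
#' @param seed integer seed for this field.
#' @param channels which channels to render (subset of `DAPI`, `EdU`,
#'   `TUNEL`, `geminin`, `RAD51`, `p63`, `53BP1`); the ground truth always
#'   covers all markers, only rendering is restricted. Restricting channels
#'   speeds up large simulation studies that read a single marker.
#' @return `list(image = CalibratedImage, truth = GroundTruth)`.
#' @examples
#' fov <- generateFov(sliceScenario(nNuclei = 20L, widthPx = 160L,
#'                                  heightPx = 160L), "untreated", seed = 7)
#' fov$truth
#' @export
generateFov <- function(scenario, condition, seed,
                        channels = c("DAPI", "EdU", "TUNEL", "geminin",
                                     "RAD51", "p63", "53BP1")) {
  stopifnot(is(scenario, "SliceScenario"))
  channels <- match.arg(channels, several.ok = TRUE)
  te <- scenario@treatmentEffect
  if (!condition %in% names(te))
    stop("condition '", condition, "' not in scenario treatment map (",
         paste(names(te), collapse = ", "), ")")
  eff <- te[[condition]]
  rp <- eff[[1]]; ra <- eff[[2]]; rf <- eff[[3]]

  withLocalSeed(seed, {
    w <- scenario@widthPx; h <- scenario@heightPx
    um <- scenario@umPerPx
    pe <- scenario@fracEdu * rp
    pt <- scenario@fracTunel * ra
    if (pe > 1 || pt > 1) {
      warning(sprintf(
        "effective positive fraction exceeds 1 (EdU %.2f, TUNEL %.2f); clipped",
        pe, pt))
      pe <- min(1, pe); pt <- min(1, pt)
    }
    n <- scenario@nNuclei
    params <- placeNuclei(w, h, n, scenario@nucleusRadiusUm, um,
                          attemptBound = max(1000L, 200L * n))
    lab <- matrix(0L, h, w)
    for (k in seq_len(nrow(params)))
      lab <- rasteriseNucleus(lab, k, params[k, ])
    # drop nuclei whose raster is empty (possible only for degenerate sizes)
    counts <- tabulate(lab, nbins = max(nrow(params), 1L))
    keep <- which(counts > 0L)
    if (length(keep) < nrow(params)) {
      remap <- integer(nrow(params))
      remap[keep] <- seq_along(keep)
      lab[] <- ifelse(lab > 0L, remap[lab], 0L)
      params <- params[keep, , drop = FALSE]
    }
    n <- nrow(params)

    flags <- data.frame(
      edu     = stats::runif(n) < pe,
      tunel   = stats::runif(n) < pt,
      geminin = stats::runif(n) < scenario@fracGeminin,
      p63     = stats::runif(n) < scenario@fracP63)

    # mask centroids as truth centers; per-label pixel index cache
    if (n > 0) {
      idx <- which(lab > 0L)
      labv <- lab[idx]
      ys <- ((idx - 1L) %% h) + 1L
      xs <- ((idx - 1L) %/% h) + 1L
      cxs <- as.numeric(rowsum(xs, labv) / tabulate(labv, n))
      cys <- as.numeric(rowsum(ys, labv) / tabulate(labv, n))
      idxByLab <- split(idx, factor(labv, levels = seq_len(n)))
    } else {
      cxs <- cys <- numeric(0)
      idxByLab <- list()
    }

    nuclei <- data.frame(label = seq_len(n), cx = cxs, cy = cys,
                         radiusUm = params$radiusUm, flags,
                         fociCount = integer(n), rad51Count = integer(n))

    msl <- scenario@focusSizeLog
    minSep <- max(2.5, 4 * sqrt(exp(msl[1]) / um^2 / (2 * pi * log(2))))
    fociList <- list()
    lambda53 <- scenario@fociLambda * rf
    for (k in seq_len(n)) {
      maskIdx <- idxByLab[[k]]
      m53 <- stats::rpois(1, lambda53)
      mR <- stats::rpois(1, scenario@rad51Lambda)
      cen <- sampleFocusCenters(maskIdx, m53 + mR, minSep, h)
      if (nrow(cen) == 0L) { nuclei$fociCount[k] <- 0L; next }
      areas <- stats::rlnorm(m53 + mR, msl[1], msl[2])
      chan <- rep(c("53BP1", "RAD51"), c(m53, mR))
      z <- ifelse(chan == "53BP1", stats::runif(m53 + mR, 0, 2), NA_real_)
      fociList[[length(fociList) + 1L]] <- data.frame(
        label = k, channel = chan, cx = cen$cx, cy = cen$cy,
        areaUm2 = areas, z = z)
      nuclei$fociCount[k] <- m53
      nuclei$rad51Count[k] <- mR
    }
    foci <- if (length(fociList)) do.call(rbind, fociList) else
      data.frame(label = integer(0), channel = character(0),
                 cx = integer(0), cy = integer(0), areaUm2 = numeric(0),
                 z = numeric(0))

    # shared illumination background: low-order polynomial surface
    X <- matrix(rep(seq_len(w) / w, each = h), h, w)
    Y <- matrix(rep(seq_len(h) / h, times = w), h, w)
    cf <- stats::runif(5)
    poly <- cf[1] * X + cf[2] * Y + cf[3] * X * Y + cf[4] * X^2 + cf[5] * Y^2
    rng <- range(poly)
    polyN <- if (diff(rng) > 0) (poly - rng[1]) / diff(rng) else poly * 0
    bg <- .render$baseBackground +
      scenario@noise[["backgroundAmplitude"]] * polyN

    rn <- function(p, n) pmax(0, stats::rnorm(n, p[["mean"]], p[["sd"]]))
    paint <- function(posLevel, negLevel = NULL) {
      img <- bg
      for (k in seq_len(n)) {
        lvl <- if (is.null(negLevel)) posLevel[k] else
          if (negLevel$flag[k]) posLevel[k] else negLevel$level[k]
        img[idxByLab[[k]]] <- img[idxByLab[[k]]] + lvl
      }
      img
    }
    noisy2 <- function(m) applyCameraNoise(m, scenario@noise)
    marker <- function(flag, posPar) {
      pos <- rn(posPar, n); neg <- rn(.render$markerNeg, n)
      paint(pos, list(flag = flag, level = neg))
    }
    amps <- sig <- isR <- NULL
    if (nrow(foci) > 0) {
      amps <- pmax(0, stats::rnorm(nrow(foci), .render$focusAmp[["mean"]],
                                   .render$focusAmp[["sd"]]))
      sig <- sqrt((foci$areaUm2 / um^2) / (2 * pi * log(2)))
      isR <- foci$channel == "RAD51"
    }
    px <- list()
    for (ch in channels) {
      px[[ch]] <- switch(ch,
        DAPI = noisy2(paint(rn(.render$dapiNucleus, n))),
        EdU = noisy2(marker(flags$edu, .render$markerPos)),
        TUNEL = noisy2(marker(flags$tunel, .render$markerPos)),
        geminin = noisy2(marker(flags$geminin, .render$markerPos)),
        p63 = noisy2(marker(flags$p63, .render$p63Pos)),
        RAD51 = {
          base <- paint(rn(.render$panNuclear, n))
          if (!is.null(isR) && any(isR))
            base <- renderSpots(base, foci$cx[isR], foci$cy[isR],
                                sig[isR], amps[isR])
          noisy2(base)
        },
        `53BP1` = {
          base <- paint(rn(.render$panNuclear, n))
          st <- array(0L, dim = c(h, w, 3))
          for (p in 1:3) {
            plane <- base
            if (!is.null(isR) && any(!isR)) {
              wz <- exp(-((p - 1) - foci$z[!isR])^2 /
                          (2 * .render$zSigma^2))
              plane <- renderSpots(plane, foci$cx[!isR], foci$cy[!isR],
                                   sig[!isR], amps[!isR] * wz)
            }
            st[, , p] <- noisy2(plane)
          }
          st
        })
    }
    img <- CalibratedImage(px, umPerPx = um,
                           zStepUm = if ("53BP1" %in% channels) 1
                                     else NA_real_)

    fractions <- if (n > 0)
      c(edu = mean(flags$edu), tunel = mean(flags$tunel),
        geminin = mean(flags$geminin), p63 = mean(flags$p63))
    else c(edu = NA_real_, tunel = NA_real_, geminin = NA_real_,
           p63 = NA_real_)
    truth <- new("GroundTruth", labelImage = lab, nuclei = nuclei,
                 foci = foci, fractions = fractions, condition = condition,
                 umPerPx = um)
    list(image = img, truth = truth)
  })
}

#' Write a synthetic experiment to disk
#'
#' Generates `nFov` fields per condition, writes each as a 16-bit multipage
#' TIFF (one page per 2D channel, three pages bottom-to-top for the 53BP1
#' stack), plus a manifest CSV and a per-nucleus truth CSV. Per-field seeds
#' are derived deterministically from `scenario@seed`, so repeating the call
#' reproduces byte-identical images.
#'
#' @param scenario a [SliceScenario-class].
#' @param design data.frame with columns `condition`, `nFov` (or a named
#'   integer vector); every condition must exist in the scenario map.
#' @param outDir output directory (created if needed).
#' @param sampleId sample identifier written to the manifest.
#' @param overwrite logical; refuse to clobber an existing manifest unless
#'   `TRUE`.
#' @return invisibly, `list(manifest = <path>, truth = <path>,
#'   rows = <manifest data.frame>)`.
#' @export
generateExperiment <- function(scenario, design, outDir, sampleId = "S1",
                               overwrite = FALSE) {
  stopifnot(is(scenario, "SliceScenario"))
  if (!is.data.frame(design)) {
    design <- data.frame(condition = names(design),
                         nFov = as.integer(design))
  }
  stopifnot(all(c("condition", "nFov") %in% names(design)))
  bad <- setdiff(design$condition, names(scenario@treatmentEffect))
  if (length(bad))
    stop("conditions not in scenario: ", paste(bad, collapse = ", "))
  dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
  manifestPath <- file.path(outDir, "manifest.csv")
  truthPath <- file.path(outDir, "truth.csv")
  if (file.exists(manifestPath) && !overwrite)
    stop("manifest already exists at ", manifestPath,
         "; use overwrite = TRUE to replace it")

  chanList <- "DAPI;EdU;TUNEL;geminin;RAD51;p63;53BP1:3"
  rows <- list(); truthRows <- list(); counter <- 0L
  for (i in seq_len(nrow(design))) {
    cond <- design$condition[i]
    for (j in seq_len(design$nFov[i])) {
      counter <- counter + 1L
      fovSeed <- scenario@seed + counter
      fov <- generateFov(scenario, cond, fovSeed)
      fn <- sprintf("%s_%s_fov%02d.tif", sampleId,
                    gsub("[^A-Za-z0-9._-]", "-", cond), j)
      writeCalibratedImage(fov$image, file.path(outDir, fn))
      rows[[counter]] <- data.frame(
        sample_id = sampleId, condition = cond, fov_index = j, file = fn,
        um_per_px = scenario@umPerPx, channel_list = chanList)
      tn <- fov$truth@nuclei
      if (nrow(tn) > 0)
        truthRows[[length(truthRows) + 1L]] <- data.frame(
          file = fn, nucleus_label = tn$label, cx = tn$cx, cy = tn$cy,
          edu = tn$edu, tunel = tn$tunel, geminin = tn$geminin,
          p63 = tn$p63, foci_count = tn$fociCount,
          rad51_count = tn$rad51Count)
    }
  }
  manifest <- if (counter > 0) do.call(rbind, rows) else
    data.frame(sample_id = character(0), condition = character(0),
               fov_index = integer(0), file = character(0),
               um_per_px = numeric(0), channel_list = character(0))
  utils::write.csv(manifest, manifestPath, row.names = FALSE)
  truthDf <- if (length(truthRows)) do.call(rbind, truthRows) else
    data.frame(file = character(0), nucleus_label = integer(0))
  utils::write.csv(truthDf, truthPath, row.names = FALSE)
  invisible(list(manifest = manifestPath, truth = truthPath,
                 rows = manifest))
}
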