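# Classical nucleus and focus segmentation.
#
# Nuclei: rolling-ball-style background subtraction (grayscale opening on a
# downsampled copy), Gaussian smoothing, Otsu threshold, hole filling and a
# distance-transform watershed to split touching nuclei. Foci: white top-hat
# background suppression followed by scale-normalized Laplacian-of-Gaussian
# blob detection, with each blob grown to its half-maximum region for
# sizing. The module boundary (NucleusTable / focus records) would equally
# accommodate a learned segmentation backend.

ebi <- function(m) EBImage::Image(m)

oddAtLeast <- function(x, lo = 3L) {
  v <- max(lo, as.integer(round(x)))
  if (v %% 2L == 0L) v + 1L else v
}

# grayscale-opening background estimate computed at reduced resolution;
# the input is replicate-padded by the structuring radius so the estimate
# carries no edge artifacts after cropping
estimateBackground <- function(x, radiusPx, shrink = 4L) {
  h <- nrow(x); w <- ncol(x)
  p <- as.integer(ceiling(radiusPx))
  xp <- x[c(rep(1L, p), seq_len(h), rep(h, p)),
          c(rep(1L, p), seq_len(w), rep(w, p)), drop = FALSE]
  hp <- nrow(xp); wp <- ncol(xp)
  hs <- max(8L, as.integer(hp / shrink))
  small <- EBImage::resize(ebi(xp), w = hs)
  brush <- EBImage::makeBrush(oddAtLeast(2 * radiusPx / shrink + 1), "disc")
  op <- EBImage::opening(small, brush)
  bg <- EBImage::resize(op, w = hp, h = wp)
  m <- as.matrix(EBImage::imageData(bg))
  pmin(m[p + seq_len(h), p + seq_len(w), drop = FALSE], x)
}

# per-label summaries from a label image plus the raw channels
labelStats <- function(lab, image) {
  h <- nrow(lab); w <- ncol(lab)
  n <- max(lab)
  if (n == 0L)
    return(emptyNucleusDf(image@channels))
  idx <- which(lab > 0L)
  labv <- lab[idx]
  areaPx <- tabulate(labv, n)
  ys <- ((idx - 1L) %% h) + 1L
  xs <- ((idx - 1L) %/% h) + 1L
  cx <- as.numeric(rowsum(as.numeric(xs), labv) / areaPx)
  cy <- as.numeric(rowsum(as.numeric(ys), labv) / areaPx)
  borderLabs <- unique(c(lab[1, ], lab[h, ], lab[, 1], lab[, w]))
  df <- data.frame(label = seq_len(n), areaPx = areaPx,
                   areaUm2 = areaPx * image@umPerPx^2,
                   cx = cx, cy = cy,
                   touchesBorder = seq_len(n) %in% borderLabs)
  for (ch in image@channels) {
    a <- image@pixels[[ch]]
    if (length(dim(a)) == 3L) a <- maxProject(a)
    df[[paste0("mean_", ch)]] <-
      as.numeric(rowsum(as.numeric(a[idx]), labv) / areaPx)
  }
  df
}

emptyNucleusDf <- function(channels) {
  df <- data.frame(label = integer(0), areaPx = integer(0),
                   areaUm2 = numeric(0), cx = numeric(0), cy = numeric(0),
                   touchesBorder = logical(0))
  for (ch in channels) df[[paste0("mean_", ch)]] <- numeric(0)
  df
}

#' Segment nuclei from a nuclear-stain channel
#'
#' Background-subtracted (grayscale opening with an effective radius of
#' about four mean nucleus radii), Gaussian-smoothed, Otsu-thresholded,
#' hole-filled, and split by a distance-transform watershed. Returns the
#' unfiltered [NucleusTable-class]; apply [filterNuclei()] afterwards for
#' the border and minimum-area exclusions. Mean intensities of every
#' channel (z-stacks via their maximum projection) are attached per
#' nucleus. The detected count is invariant under rescaling the image by a
#' positive constant, and a blank (zero-variance) channel yields an empty
#' table rather than an error.
#'
#' @param image a [CalibratedImage-class].
#' @param channel channel to segment (default `"DAPI"`).
#' @param nucleusRadiusUm expected mean nucleus radius in micrometres;
#'   sets the background-subtraction and smoothing scales.
#' @param smoothSigmaPx Gaussian pre-smoothing sigma in pixels.
#' @param watershedTolerance minimum distance-map depth separating two
#'   nuclei seeds (pixels).
#' @return a [NucleusTable-class].
#' @export
segmentNuclei <- function(image, channel = "DAPI", nucleusRadiusUm = 4,
                          smoothSigmaPx = 2, watershedTolerance = 1) {
  stopifnot(is(image, "CalibratedImage"))
  raw <- getChannel(image, channel)
  if (length(dim(raw)) == 3L) raw <- maxProject(raw)
  x <- matrix(as.numeric(raw), nrow = nrow(raw))
  if (max(x) == min(x)) {
    return(new("NucleusTable", labelImage = matrix(0L, nrow(x), ncol(x)),
               nuclei = emptyNucleusDf(image@channels),
               umPerPx = image@umPerPx,
               excluded = c(border = 0L, smallArea = 0L)))
  }
  x <- x / max(x)
  radiusPx <- nucleusRadiusUm / image@umPerPx
  bg <- estimateBackground(x, radiusPx * 4)
  xs <- pmax(x - bg, 0)
  sm <- as.matrix(EBImage::imageData(EBImage::gblur(ebi(xs), boundary = "replicate",
                                                    sigma = smoothSigmaPx)))
  th <- EBImage::otsu(ebi(sm), range = c(0, 1))
  mask <- sm > th
  mask <- as.matrix(EBImage::imageData(EBImage::fillHull(ebi(mask)))) > 0
  dm <- EBImage::distmap(ebi(mask))
  dms <- EBImage::gblur(dm, sigma = max(1, smoothSigmaPx / 2), boundary = "replicate")
  dms[mask == 0] <- 0
  labs <- EBImage::watershed(dms, tolerance = watershedTolerance, ext = 1)
  lab <- matrix(as.integer(EBImage::imageData(labs)), nrow = nrow(x))
  # relabel consecutively (watershed can skip ids after tolerance merging)
  u <- sort(unique(lab[lab > 0L]))
  if (length(u) && !identical(u, seq_along(u))) {
    remap <- integer(max(u)); remap[u] <- seq_along(u)
    lab[lab > 0L] <- remap[lab[lab > 0L]]
  }
  new("NucleusTable", labelImage = lab, nuclei = labelStats(lab, image),
      umPerPx = image@umPerPx, excluded = c(border = 0L, smallArea = 0L))
}

#' Build a NucleusTable from generator ground truth
#'
#' Bypasses segmentation by adopting the generator's label image, then
#' measures areas, border contact and per-channel mean intensities exactly
#' as [segmentNuclei()] would. This is the truth-passthrough hook used to
#' test scoring independently of segmentation quality.
#'
#' @param truth a [GroundTruth-class].
#' @param image the matching [CalibratedImage-class].
#' @return a [NucleusTable-class].
#' @export
nucleusTableFromTruth <- function(truth, image) {
  stopifnot(is(truth, "GroundTruth"), is(image, "CalibratedImage"))
  lab <- truth@labelImage
  new("NucleusTable", labelImage = lab, nuclei = labelStats(lab, image),
      umPerPx = image@umPerPx, excluded = c(border = 0L, smallArea = 0L))
}

#' Apply the border and minimum-area nucleus filters
#'
#' Removes every nucleus touching the image border (any mask pixel on the
#' first or last row or column) and every nucleus strictly smaller than
#' `minAreaUm2`; a nucleus of exactly the boundary area is retained.
#' Retained rows are unchanged (labels are not renumbered) and the removed
#' labels are zeroed in the label image. Exclusion counts are accumulated
#' in the `excluded` slot. The operation is idempotent.
#'
#' @param table a [NucleusTable-class].
#' @param minAreaUm2 minimum nucleus area in square micrometres (default 10).
#' @return the filtered [NucleusTable-class].
#' @export
filterNuclei <- function(table, minAreaUm2 = 10) {
  stopifnot(is(table, "NucleusTable"))
  df <- table@nuclei
  if (nrow(df) == 0L) return(table)
  dropBorder <- df$touchesBorder
  dropSmall <- !dropBorder & df$areaUm2 < minAreaUm2
  keep <- !dropBorder & !dropSmall
  lab <- table@labelImage
  if (any(!keep)) {
    gone <- df$label[!keep]
    lab[lab %in% gone] <- 0L
  }
  new("NucleusTable", labelImage = lab, nuclei = df[keep, , drop = FALSE],
      umPerPx = table@umPerPx,
      excluded = table@excluded +
        c(border = sum(dropBorder), smallArea = sum(dropSmall)))
}

# scale-normalized LoG kernel (negated, so bright blobs give positive peaks)
logKernel <- function(sigma) {
  r <- max(2L, ceiling(4 * sigma))
  d <- (-r):r
  xx <- outer(d^2, d^2, `+`)
  g <- exp(-xx / (2 * sigma^2))
  g <- g / sum(g)
  k <- -sigma^2 * (xx - 2 * sigma^2) / sigma^4 * g
  k - mean(k)
}

#' Detect and size foci inside segmented nuclei
#'
#' White top-hat suppression of the diffuse nuclear signal, followed by
#' Laplacian-of-Gaussian blob detection at scales spanning the expected
#' focus area; each detected blob is grown to the connected region above
#' half of its peak value, giving its area in square micrometres. Foci whose
#' peak falls outside every nucleus in `nuclei` are discarded, so passing a
#' filtered, p63-gated table implements "foci inside p63 nuclei". Blobs
#' closer than the detection scale merge and count once.
#'
#' @param image a [CalibratedImage-class].
#' @param fociChannel 2D focus channel label; a z-stack must be
#'   maximum-projected first (see [maxProject()]).
#' @param nuclei the filtered [NucleusTable-class] to gate on.
#' @param focusAreaRangeUm2 expected range of focus areas (um^2); sets the
#'   LoG scale range.
#' @param nScales number of log-spaced LoG scales.
#' @param minResponse floor on the scale-normalized LoG response (on
#'   intensities normalized to `[0, 1]`) for a peak to count; the working
#'   threshold is the larger of this floor and five robust (MAD) noise
#'   standard deviations of the response, so detection adapts to the
#'   image's noise level.
#' @param minIntensity floor on the background-suppressed peak intensity;
#'   like `minResponse`, raised automatically to three noise standard
#'   deviations when the image is noisy.
#' @return data.frame with one row per focus: `nucleusLabel`, `cx`, `cy`,
#'   `areaUm2`, `peak`, `sigmaPx`.
#' @export
detectFoci <- function(image, fociChannel, nuclei,
                       focusAreaRangeUm2 = c(0.4, 4), nScales = 6,
                       minResponse = 0.05, minIntensity = 0.1) {
  stopifnot(is(image, "CalibratedImage"), is(nuclei, "NucleusTable"))
  fc <- getChannel(image, fociChannel)
  if (length(dim(fc)) == 3L)
    stop("focus channel '", fociChannel,
         "' is a z-stack; apply maxProject() first")
  x <- matrix(as.numeric(fc), nrow = nrow(fc))
  x <- if (is.integer(fc)) x / 65535 else x / max(x, 1e-12)
  um <- image@umPerPx
  empty <- data.frame(nucleusLabel = integer(0), cx = integer(0),
                      cy = integer(0), areaUm2 = numeric(0),
                      peak = numeric(0), sigmaPx = numeric(0))
  if (nrow(nuclei@nuclei) == 0L) return(empty)

  # sigma of a Gaussian spot whose half-maximum area is a (in px^2)
  sigmaOfArea <- function(a) sqrt((a / um^2) / (2 * pi * log(2)))
  sigmas <- exp(seq(log(sigmaOfArea(focusAreaRangeUm2[1])),
                    log(sigmaOfArea(focusAreaRangeUm2[2])),
                    length.out = nScales))
  sigmas <- pmax(sigmas, 0.6)

  brush <- EBImage::makeBrush(oddAtLeast(6 * max(sigmas)), "disc")
  th <- as.matrix(EBImage::imageData(EBImage::whiteTopHat(ebi(x), brush)))

  h <- nrow(x); w <- ncol(x)
  # per-scale responses are z-scored against their own robust (MAD) noise
  # level, so the best scale is the matched filter and the detection
  # threshold adapts to the image's noise; clean images fall back to the
  # raw-response floor (their MAD is essentially zero)
  # detection uses the z maps; the spot-scale estimate uses the raw
  # response, whose maximum over scales sits at the true spot sigma
  # (the z optimum is biased towards larger scales)
  R <- matrix(-Inf, h, w); Z <- matrix(-Inf, h, w)
  Rsig <- matrix(sigmas[1], h, w)
  for (s in sigmas) {
    resp <- as.matrix(EBImage::imageData(
      EBImage::filter2(ebi(th), logKernel(s), boundary = "replicate")))
    madS <- stats::mad(resp, center = stats::median(resp))
    z <- resp / max(madS, 1e-12)
    Z <- pmax(Z, z)
    upd <- resp > R
    R[upd] <- resp[upd]
    Rsig[upd] <- s
  }
  # robust pixel-noise estimate from adjacent differences of the image
  noiseSd <- stats::mad(x[, -1] - x[, -w]) / sqrt(2)
  intThr <- max(minIntensity, 3.5 * noiseSd)
  localMax <- Z >= as.matrix(EBImage::imageData(
    EBImage::dilate(ebi(Z), EBImage::makeBrush(3, "box"))))
  cand <- which(localMax & R > minResponse & Z > 5 & th > intThr)
  if (!length(cand)) return(empty)
  cy <- ((cand - 1L) %% h) + 1L
  cx <- ((cand - 1L) %/% h) + 1L
  ord <- order(Z[cand], decreasing = TRUE)
  keep <- logical(length(cand))
  for (i in ord) {
    if (any(keep & (cx - cx[i])^2 + (cy - cy[i])^2 < 2.25)) next
    keep[i] <- TRUE
  }
  cand <- cand[keep]; cx <- cx[keep]; cy <- cy[keep]

  lab <- nuclei@labelImage
  inNucleus <- lab[cbind(cy, cx)]
  sel <- inNucleus > 0L
  outside <- sum(!sel)
  cand <- cand[sel]; cx <- cx[sel]; cy <- cy[sel]
  nl <- inNucleus[sel]
  if (!length(cand)) {
    attr(empty, "outsideCount") <- outside
    return(empty)
  }

  # size each blob as its half-maximum region, measured on a mildly
  # smoothed top-hat (robust to pixel noise) and deflated analytically for
  # the smoothing-induced widening of a Gaussian spot
  smoothSigma <- 0.8
  ths <- as.matrix(EBImage::imageData(EBImage::gblur(ebi(th), boundary = "replicate",
                                                     sigma = smoothSigma)))
  # the top-hat of a noisy image sits on a positive noise floor; half
  # maximum is measured above that floor, not above zero
  floorVal <- stats::median(ths)
  areas <- numeric(length(cand))
  for (i in seq_along(cand)) {
    # refine to the local smoothed-intensity maximum so the half-maximum
    # reference is the actual spot peak, not a noise-shifted neighbor
    rr <- max(1L, cy[i] - 2L):min(h, cy[i] + 2L)
    rc <- max(1L, cx[i] - 2L):min(w, cx[i] + 2L)
    loc <- which.max(ths[rr, rc, drop = FALSE])
    py <- rr[((loc - 1L) %% length(rr)) + 1L]
    px <- rc[((loc - 1L) %/% length(rr)) + 1L]
    s <- Rsig[py + (px - 1L) * h]
    r <- ceiling(5 * s)
    rows <- max(1L, py - r):min(h, py + r)
    cols <- max(1L, px - r):min(w, px + r)
    win <- ths[rows, cols, drop = FALSE]
    pk <- ths[py, px]
    thr <- if (pk > floorVal) floorVal + (pk - floorVal) / 2 else pk / 2
    # threshold on a 2x upsampled window for sub-pixel area precision
    up <- 2L
    winU <- as.matrix(EBImage::imageData(EBImage::resize(
      ebi(win), w = up * nrow(win), h = up * ncol(win))))
    cc <- EBImage::bwlabel(ebi(winU >= thr))
    ctr <- as.integer(EBImage::imageData(cc)[
      up * (py - rows[1]) + 1L, up * (px - cols[1]) + 1L])
    raw <- (if (ctr > 0) sum(EBImage::imageData(cc) == ctr) else 1L) / up^2
    # for a Gaussian spot, smoothing widens the half-maximum area by
    # exactly 2*pi*ln(2)*smoothSigma^2 pixels; subtract that constant
    areas[i] <- max(raw - 2 * pi * log(2) * smoothSigma^2, 0.5)
  }
  out <- data.frame(nucleusLabel = nl, cx = cx, cy = cy,
                    areaUm2 = areas * um^2, peak = th[cand],
                    sigmaPx = Rsig[cand])
  attr(out, "outsideCount") <- outside
  out
}

#' Match a segmentation against ground-truth labels
#'
#' Greedy one-to-one matching of predicted and truth nuclei by intersection
#' over union (IoU). A predicted nucleus counts as a true positive when its
#' matched IoU reaches `iouThreshold`.
#'
#' @param pred a [NucleusTable-class] or an integer label matrix.
#' @param truthLab integer ground-truth label matrix (same size).
#' @param iouThreshold IoU at or above which a match counts (default 0.5).
#' @return list with `tp`, `fp`, `fn`, `precision`, `recall`, `f1` and the
#'   matched pair table.
#' @export
matchNuclei <- function(pred, truthLab, iouThreshold = 0.5) {
  predLab <- if (is(pred, "NucleusTable")) pred@labelImage else pred
  stopifnot(identical(dim(predLab), dim(truthLab)))
  predIds <- sort(unique(predLab[predLab > 0L]))
  truthIds <- sort(unique(truthLab[truthLab > 0L]))
  nP <- length(predIds); nT <- length(truthIds)
  if (nP == 0L || nT == 0L) {
    f1 <- if (nP + nT == 0L) 1 else 0
    return(list(tp = 0L, fp = nP, fn = nT, precision = as.numeric(nP == 0),
                recall = as.numeric(nT == 0), f1 = f1,
                pairs = data.frame(pred = integer(0), truth = integer(0),
                                   iou = numeric(0))))
  }
  both <- predLab > 0L & truthLab > 0L
  key <- as.numeric(predLab[both]) * (max(truthIds) + 1) +
    as.numeric(truthLab[both])
  tab <- table(key)
  keys <- as.numeric(names(tab))
  p <- floor(keys / (max(truthIds) + 1))
  t <- keys - p * (max(truthIds) + 1)
  inter <- as.numeric(tab)
  aP <- tabulate(predLab[predLab > 0L], max(predIds))
  aT <- tabulate(truthLab[truthLab > 0L], max(truthIds))
  iou <- inter / (aP[p] + aT[t] - inter)
  ord <- order(iou, decreasing = TRUE)
  usedP <- logical(max(predIds)); usedT <- logical(max(truthIds))
  pairs <- list()
  for (i in ord) {
    if (iou[i] < iouThreshold) break
    if (usedP[p[i]] || usedT[t[i]]) next
    usedP[p[i]] <- TRUE; usedT[t[i]] <- TRUE
    pairs[[length(pairs) + 1L]] <- data.frame(pred = p[i], truth = t[i],
                                              iou = iou[i])
  }
  tp <- length(pairs)
  pairsDf <- if (tp) do.call(rbind, pairs) else
    data.frame(pred = integer(0), truth = integer(0), iou = numeric(0))
  precision <- tp / nP; recall <- tp / nT
  f1 <- if (precision + recall == 0) 0 else
    2 * precision * recall / (precision + recall)
  list(tp = tp, fp = nP - tp, fn = nT - tp, precision = precision,
       recall = recall, f1 = f1, pairs = pairsDf)
}
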