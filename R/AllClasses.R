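#' @import methods
NULL

#' CalibratedImage: a multichannel fluorescence field of view with calibration
#'
#' Container for one imaged field of view (FoV). Each channel is a 2D
#' intensity matrix (rows = y, columns = x) or, for a focus z-stack such as
#' 53BP1, a 3D array with planes ordered bottom to top. All channels share
#' the same width and height, and the physical pixel size (micrometres per
#' pixel) travels with the pixel data so that downstream areas are always
#' reported in square micrometres.
#'
#' @slot pixels named list of numeric matrices (y by x) or 3D arrays
#'   (y by x by plane), one per channel, nonnegative intensities.
#' @slot channels character vector of channel labels, in page order.
#' @slot umPerPx positive scalar, micrometres per pixel.
#' @slot zStepUm positive scalar, micrometre spacing of z-planes for any
#'   3D channel; `NA` when all channels are 2D.
#'
#' @seealso [CalibratedImage()], [getChannel()], [maxProject()]
#' @export
setClass("CalibratedImage",
  representation(
    pixels   = "list",
    channels = "character",
    umPerPx  = "numeric",
    zStepUm  = "numeric"
  )
)

setValidity("CalibratedImage", function(object) {
  msg <- character()
  px <- object@pixels
  ch <- object@channels
  if (length(px) != length(ch))
    msg <- c(msg, "number of pixel arrays must match number of channels")
  if (anyDuplicated(ch))
    msg <- c(msg, "channel labels must be unique")
  if (!identical(names(px), ch) && length(px) == length(ch))
    msg <- c(msg, "pixel list names must equal channel labels")
  if (length(object@umPerPx) != 1L || !is.finite(object@umPerPx) ||
      object@umPerPx <= 0)
    msg <- c(msg, "umPerPx must be a single positive number")
  dims <- lapply(px, function(a) dim(a)[1:2])
  if (length(dims) > 1L &&
      !all(vapply(dims[-1], identical, logical(1), dims[[1]])))
    msg <- c(msg, "all channels must share the same width and height")
  has3d <- any(vapply(px, function(a) length(dim(a)) == 3L, logical(1)))
  if (has3d && (length(object@zStepUm) != 1L || is.na(object@zStepUm) ||
                object@zStepUm <= 0))
    msg <- c(msg, "a z-stack channel requires a positive zStepUm")
  if (length(msg)) msg else TRUE
})

#' Construct a CalibratedImage
#'
#' @param pixels named list of channel matrices/arrays; names are used as
#'   channel labels when `channels` is missing.
#' @param channels channel labels in order (defaults to `names(pixels)`).
#' @param umPerPx micrometres per pixel (> 0). No silent default: calibration
#'   must always be supplied.
#' @param zStepUm z-plane spacing in micrometres, required when any channel
#'   is a 3D stack.
#' @return a [CalibratedImage-class] object.
#' @examples
#' img <- CalibratedImage(list(DAPI = matrix(0L, 8, 8)), umPerPx = 0.5)
#' channelNames(img)
#' @export
CalibratedImage <- function(pixels, channels = names(pixels), umPerPx,
                            zStepUm = NA_real_) {
  if (missing(umPerPx))
    stop("umPerPx calibration is required; there is no default")
  if (is.null(channels))
    stop("channels must be named")
  names(pixels) <- channels
  new("CalibratedImage", pixels = pixels, channels = channels,
      umPerPx = as.numeric(umPerPx), zStepUm = as.numeric(zStepUm))
}

#' @describeIn CalibratedImage channel labels in page order.
#' @param x a `CalibratedImage`.
#' @export
channelNames <- function(x) x@channels

#' @describeIn CalibratedImage pixel size in micrometres per pixel.
#' @export
pixelSize <- function(x) x@umPerPx

#' Extract one channel's pixel data
#'
#' @param x a [CalibratedImage-class].
#' @param channel channel label.
#' @return the 2D matrix or 3D array for that channel.
#' @export
getChannel <- function(x, channel) {
  if (!channel %in% x@channels)
    stop("channel '", channel, "' not present; available: ",
         paste(x@channels, collapse = ", "))
  x@pixels[[channel]]
}

setMethod("show", "CalibratedImage", function(object) {
  d <- dim(object@pixels[[1]])
  planes <- vapply(object@pixels, function(a)
    if (length(dim(a)) == 3L) dim(a)[3] else 1L, integer(1))
  cat("CalibratedImage:", d[2], "x", d[1], "px at",
      object@umPerPx, "um/px\n")
  cat("  channels:", paste0(object@channels,
      ifelse(planes > 1L, paste0(" (", planes, " planes)"), ""),
      collapse = ", "), "\n")
  if (!is.na(object@zStepUm))
    cat("  z step:", object@zStepUm, "um\n")
})

#' SliceScenario: parameters of the synthetic tumor-slice generator
#'
#' Describes one simulated slice-culture experiment: the field-of-view
#' geometry, nucleus population, per-marker positive fractions, DNA-damage
#' focus statistics, per-condition treatment effects and the camera noise
#' model. The defaults emulate an HNSCC slice FoV imaged at 0.5 um/px with
#' irradiation doses (2/5/7 Gy) and a cisplatin series (3.3/16.5/33 uM)
#' as conditions.
#'
#' @slot widthPx,heightPx field-of-view size in pixels.
#' @slot umPerPx micrometres per pixel.
#' @slot nNuclei number of nuclei to place.
#' @slot nucleusRadiusUm length-2 numeric: mean and sd of nucleus radius (um).
#' @slot fracEdu,fracTunel,fracGeminin,fracP63 untreated per-cell positive
#'   fractions, each in `[0, 1]`.
#' @slot fociLambda Poisson mean of 53BP1 foci per nucleus (untreated).
#' @slot rad51Lambda Poisson mean of RAD51 foci per nucleus (post RECAP dose).
#' @slot focusSizeLog length-2 numeric: meanlog and sdlog of the log-normal
#'   true focus area (um^2), defined as the region above half-maximum.
#' @slot treatmentEffect named list; each element a numeric vector
#'   `c(rp =, ra =, rf =)` multiplying the EdU fraction, TUNEL fraction and
#'   53BP1 focus rate for that condition.
#' @slot noise named numeric `c(gain =, readSd =, backgroundAmplitude =)`,
#'   in 16-bit camera counts.
#' @slot seed base integer seed for [generateExperiment()].
#' @seealso [sliceScenario()], [generateFov()]
#' @export
setClass("SliceScenario",
  representation(
    widthPx         = "integer",
    heightPx        = "integer",
    umPerPx         = "numeric",
    nNuclei         = "integer",
    nucleusRadiusUm = "numeric",
    fracEdu         = "numeric",
    fracTunel       = "numeric",
    fracGeminin     = "numeric",
    fracP63         = "numeric",
    fociLambda      = "numeric",
    rad51Lambda     = "numeric",
    focusSizeLog    = "numeric",
    treatmentEffect = "list",
    noise           = "numeric",
    seed            = "integer"
  )
)

setValidity("SliceScenario", function(object) {
  msg <- character()
  if (object@widthPx < 1L || object@heightPx < 1L)
    msg <- c(msg, "widthPx and heightPx must be >= 1")
  if (object@umPerPx <= 0) msg <- c(msg, "umPerPx must be > 0")
  if (object@nNuclei < 0L) msg <- c(msg, "nNuclei must be >= 0")
  fr <- c(object@fracEdu, object@fracTunel, object@fracGeminin,
          object@fracP63)
  if (any(fr < 0 | fr > 1)) msg <- c(msg, "fractions must lie in [0, 1]")
  if (length(object@nucleusRadiusUm) != 2L ||
      any(object@nucleusRadiusUm <= 0))
    msg <- c(msg, "nucleusRadiusUm must be c(mean, sd), both > 0")
  if (object@fociLambda < 0 || object@rad51Lambda < 0)
    msg <- c(msg, "focus rates must be >= 0")
  if (length(object@focusSizeLog) != 2L || object@focusSizeLog[2] < 0)
    msg <- c(msg, "focusSizeLog must be c(meanlog, sdlog), sdlog >= 0")
  te <- object@treatmentEffect
  if (length(te) == 0L || is.null(names(te)) || any(names(te) == ""))
    msg <- c(msg, "treatmentEffect must be a non-empty named list")
  ok <- vapply(te, function(v)
    is.numeric(v) && length(v) == 3L && all(v >= 0), logical(1))
  if (!all(ok))
    msg <- c(msg, "each treatmentEffect entry must be c(rp, ra, rf) >= 0")
  need <- c("gain", "readSd", "backgroundAmplitude")
  if (!all(need %in% names(object@noise)) || any(object@noise < 0))
    msg <- c(msg, "noise must name nonnegative gain, readSd, backgroundAmplitude")
  if (length(msg)) msg else TRUE
})

#' Create a synthetic-slice scenario
#'
#' The defaults are the package's reference study conditions: a 512x512 px
#' FoV at 0.5 um/px holding 200 nuclei of radius 4 +/- 0.8 um; untreated
#' positive fractions of 30% EdU, 4% TUNEL, 35% geminin and 85% p63; a mean
#' of 4 53BP1 foci and 6 RAD51 foci per nucleus with log-normal focus areas
#' around 1.2 um^2; and a condition map covering untreated, 2/5/7 Gy and the
#' 3.3/16.5/33 uM cisplatin series, each condition scaling proliferation
#' (`rp`), apoptosis (`ra`) and the 53BP1 focus rate (`rf`).
#'
#' @param widthPx,heightPx FoV size in pixels.
#' @param umPerPx micrometres per pixel.
#' @param nNuclei number of nuclei.
#' @param nucleusRadiusUm `c(mean, sd)` nucleus radius in um.
#' @param fracEdu,fracTunel,fracGeminin,fracP63 untreated positive fractions.
#' @param fociLambda,rad51Lambda Poisson focus rates per nucleus.
#' @param focusSizeLog `c(meanlog, sdlog)` of the log-normal focus area (um^2).
#' @param treatmentEffect named list of `c(rp =, ra =, rf =)` per condition.
#' @param noise `c(gain =, readSd =, backgroundAmplitude =)` camera model,
#'   in 16-bit counts.
#' @param seed base seed used by [generateExperiment()].
#' @return a [SliceScenario-class] object.
#' @examples
#' sc <- sliceScenario(nNuclei = 50L)
#' sc
#' @export
sliceScenario <- function(widthPx = 512L, heightPx = 512L, umPerPx = 0.5,
                          nNuclei = 200L,
                          nucleusRadiusUm = c(4, 0.8),
                          fracEdu = 0.30, fracTunel = 0.04,
                          fracGeminin = 0.35, fracP63 = 0.85,
                          fociLambda = 4, rad51Lambda = 6,
                          focusSizeLog = c(log(1.2), 0.3),
                          treatmentEffect = list(
                            untreated    = c(rp = 1,    ra = 1,   rf = 1),
                            `2Gy`        = c(rp = 0.75, ra = 1.3, rf = 1.5),
                            `5Gy`        = c(rp = 0.50, ra = 1.6, rf = 2),
                            `7Gy`        = c(rp = 0.30, ra = 2,   rf = 2.5),
                            `cis_3.3uM`  = c(rp = 0.80, ra = 1.5, rf = 1),
                            `cis_16.5uM` = c(rp = 0.50, ra = 2.5, rf = 1),
                            `cis_33uM`   = c(rp = 0.25, ra = 4,   rf = 1)),
                          noise = c(gain = 4, readSd = 200,
                                    backgroundAmplitude = 1500),
                          seed = 1L) {
  new("SliceScenario",
      widthPx = as.integer(widthPx), heightPx = as.integer(heightPx),
      umPerPx = as.numeric(umPerPx), nNuclei = as.integer(nNuclei),
      nucleusRadiusUm = as.numeric(nucleusRadiusUm),
      fracEdu = fracEdu, fracTunel = fracTunel,
      fracGeminin = fracGeminin, fracP63 = fracP63,
      fociLambda = as.numeric(fociLambda),
      rad51Lambda = as.numeric(rad51Lambda),
      focusSizeLog = as.numeric(focusSizeLog),
      treatmentEffect = treatmentEffect,
      noise = noise, seed = as.integer(seed))
}

setMethod("show", "SliceScenario", function(object) {
  cat("SliceScenario:", object@widthPx, "x", object@heightPx, "px at",
      object@umPerPx, "um/px,", object@nNuclei, "nuclei\n")
  cat("  fractions: EdU", object@fracEdu, "| TUNEL", object@fracTunel,
      "| geminin", object@fracGeminin, "| p63", object@fracP63, "\n")
  cat("  foci/nucleus: 53BP1 lambda", object@fociLambda,
      "| RAD51 lambda", object@rad51Lambda, "\n")
  cat("  conditions:", paste(names(object@treatmentEffect), collapse = ", "),
      "\n")
})

#' GroundTruth: generator-side truth for one synthetic field of view
#'
#' @slot labelImage integer matrix, 0 = background, k = nucleus k; labels
#'   are consecutive from 1.
#' @slot nuclei data.frame, one row per nucleus: `label`, centroid `cx`/`cy`
#'   (pixels, 1-based), `radiusUm`, logical truth flags `edu`, `tunel`,
#'   `geminin`, `p63`, and counts `fociCount` (53BP1), `rad51Count`.
#' @slot foci data.frame of rendered foci: `label`, `channel`, `cx`, `cy`,
#'   `areaUm2` (true half-maximum area), `z` (plane coordinate, stacks only).
#' @slot fractions named numeric: true per-field positive fractions (the
#'   exact mean of the truth flags); all `NA` when the field holds no nuclei.
#' @slot condition condition id the field was generated under.
#' @slot umPerPx micrometres per pixel.
#' @export
setClass("GroundTruth",
  representation(
    labelImage = "matrix",
    nuclei     = "data.frame",
    foci       = "data.frame",
    fractions  = "numeric",
    condition  = "character",
    umPerPx    = "numeric"
  )
)

setValidity("GroundTruth", function(object) {
  msg <- character()
  labs <- sort(unique(as.vector(object@labelImage)))
  labs <- labs[labs > 0]
  n <- nrow(object@nuclei)
  if (n > 0 && !identical(as.integer(labs), seq_len(n)))
    msg <- c(msg, "nucleus labels must be consecutive from 1")
  if (n > 0) {
    fl <- object@nuclei[, c("edu", "tunel", "geminin", "p63")]
    want <- vapply(fl, mean, numeric(1))
    if (!isTRUE(all.equal(unname(want),
                          unname(object@fractions[c("edu", "tunel",
                                                    "geminin", "p63")]))))
      msg <- c(msg, "stored fractions must equal the mean of the truth flags")
  }
  if (nrow(object@foci) > 0) {
    idx <- cbind(round(object@foci$cy), round(object@foci$cx))
    inside <- object@labelImage[idx] == object@foci$label
    if (!all(inside))
      msg <- c(msg, "every focus center must lie inside its nucleus mask")
  }
  if (length(msg)) msg else TRUE
})

setMethod("show", "GroundTruth", function(object) {
  cat("GroundTruth (", object@condition, "): ", nrow(object@nuclei),
      " nuclei, ", nrow(object@foci), " foci\n", sep = "")
  if (nrow(object@nuclei) > 0) {
    fr <- object@fractions
    cat("  true fractions: ",
        paste(names(fr), sprintf("%.3f", fr), collapse = ", "), "\n",
        sep = "")
  }
})

#' NucleusTable: labeled nucleus segmentation with per-nucleus measurements
#'
#' Produced by [segmentNuclei()] (or [nucleusTableFromTruth()]), filtered by
#' [filterNuclei()]. Areas are in square micrometres
#' (`pixel count * umPerPx^2`); `touchesBorder` is `TRUE` iff any mask pixel
#' lies on the first or last row or column of the image. Per-channel mean
#' intensities appear as `mean_<channel>` columns (z-stack channels are
#' measured on their maximum projection).
#'
#' @slot labelImage integer matrix of nucleus labels (0 = background).
#' @slot nuclei data.frame: `label`, `areaPx`, `areaUm2`, `cx`, `cy`,
#'   `touchesBorder`, then `mean_<channel>` columns.
#' @slot umPerPx micrometres per pixel.
#' @slot excluded named integer vector of per-stage exclusion counts
#'   (`border`, `smallArea`), filled in by [filterNuclei()].
#' @export
setClass("NucleusTable",
  representation(
    labelImage = "matrix",
    nuclei     = "data.frame",
    umPerPx    = "numeric",
    excluded   = "integer"
  )
)

setValidity("NucleusTable", function(object) {
  msg <- character()
  n <- object@nuclei
  if (nrow(n) > 0) {
    if (anyDuplicated(n$label) || any(n$label <= 0))
      msg <- c(msg, "labels must be positive and unique")
    if (!isTRUE(all.equal(n$areaUm2, n$areaPx * object@umPerPx^2)))
      msg <- c(msg, "areaUm2 must equal areaPx * umPerPx^2")
  }
  if (object@umPerPx <= 0) msg <- c(msg, "umPerPx must be > 0")
  if (length(msg)) msg else TRUE
})

setMethod("show", "NucleusTable", function(object) {
  cat("NucleusTable:", nrow(object@nuclei), "nuclei at", object@umPerPx,
      "um/px\n")
  if (length(object@excluded))
    cat("  excluded:", paste(names(object@excluded), object@excluded,
                             collapse = ", "), "\n")
  if (nrow(object@nuclei) > 0)
    cat("  area (um^2): median",
        round(stats::median(object@nuclei$areaUm2), 1), "\n")
})

#' @describeIn NucleusTable the per-nucleus measurement data.frame.
#' @param x a `NucleusTable`.
#' @export
nucleusData <- function(x) x@nuclei

#' @describeIn NucleusTable the integer label image.
#' @export
labelImage <- function(x) x@labelImage
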