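# Per-nucleus assay readouts: marker positivity, cell records, the RECAP
# homologous-recombination score, focus density per nuclear volume, and
# per-field summaries.

# exact 1D Otsu: threshold maximizing between-class variance over midpoints
otsuThresholdMeans <- function(v) {
  u <- sort(unique(v))
  if (length(u) < 2L) return(u[1])
  cuts <- (u[-1] + u[-length(u)]) / 2
  best <- -Inf; bestCut <- cuts[1]
  for (ct in cuts) {
    lo <- v[v <= ct]; hi <- v[v > ct]
    bv <- length(lo) * length(hi) / length(v)^2 * (mean(hi) - mean(lo))^2
    if (bv > best) { best <- bv; bestCut <- ct }
  }
  bestCut
}

#' Call per-nucleus marker positivity
#'
#' A nucleus is positive when its per-nucleus mean intensity in `channel`
#' exceeds a threshold. Three threshold rules are available:
#' `"otsu"` (default) computes an Otsu threshold on the distribution of
#' per-nucleus mean intensities within the field, which is parameter-free
#' and suits the bimodal intensity distributions of binary markers;
#' `"absolute"` uses the supplied `threshold` in camera counts;
#' `"truth"` passes generator truth flags through unchanged (a test hook,
#' usable when nuclei were built with [nucleusTableFromTruth()]).
#'
#' @param nuclei a [NucleusTable-class] with `mean_<channel>` measured.
#' @param channel marker channel label.
#' @param rule one of `"otsu"`, `"absolute"`, `"truth"`.
#' @param threshold intensity threshold, required for `rule = "absolute"`.
#' @param truthFlags logical vector named by nucleus label, required for
#'   `rule = "truth"`.
#' @return logical vector, one flag per retained nucleus (named by label).
#' @export
callPositivity <- function(nuclei, channel,
                           rule = c("otsu", "absolute", "truth"),
                           threshold = NULL, truthFlags = NULL) {
  stopifnot(is(nuclei, "NucleusTable"))
  rule <- match.arg(rule)
  df <- nuclei@nuclei
  col <- paste0("mean_", channel)
  if (!col %in% names(df))
    stop("no mean intensity recorded for channel '", channel, "'")
  means <- df[[col]]
  flags <- switch(rule,
    otsu = {
      if (length(means) < 2L)
        stop("Otsu positivity needs at least 2 nuclei; ",
             "use rule = 'absolute' with an explicit threshold")
      means > otsuThresholdMeans(means)
    },
    absolute = {
      if (is.null(threshold) || !is.finite(threshold))
        stop("rule = 'absolute' requires a finite threshold")
      means > threshold
    },
    truth = {
      if (is.null(truthFlags))
        stop("rule = 'truth' requires truthFlags named by nucleus label")
      fl <- truthFlags[as.character(df$label)]
      if (anyNA(fl))
        stop("truthFlags missing for some nucleus labels")
      as.logical(fl)
    })
  names(flags) <- df$label
  flags
}

#' Estimate per-nucleus focus density per nuclear volume
#'
#' The nuclear volume is estimated from the projected 2D area as the
#' sphere-equivalent volume `V = (4/3) * pi * (area / pi)^(3/2)`, i.e. the
#' sphere whose equatorial cross-section equals the measured area. This is
#' a fixed monotone estimator: between-condition comparisons do not depend
#' on the choice. Density is `focusCount / V` in foci per cubic micrometre.
#'
#' @param focusCount nonnegative integer vector.
#' @param areaUm2 matching vector of projected nuclear areas (um^2), > 0.
#' @return numeric vector of densities (foci/um^3).
#' @examples
#' fociDensity(4, pi)  # radius-1-um nucleus: 4 / (4*pi/3) = 3/pi
#' @export
fociDensity <- function(focusCount, areaUm2) {
  if (any(!is.finite(areaUm2)) || any(areaUm2 <= 0))
    stop("areaUm2 must be positive; got a zero or non-finite nuclear area")
  if (any(focusCount < 0)) stop("focusCount must be nonnegative")
  volume <- (4 / 3) * pi * (areaUm2 / pi)^(3 / 2)
  focusCount / volume
}

#' Assemble per-cell records from nuclei, positivity calls and foci
#'
#' @param nuclei a filtered [NucleusTable-class].
#' @param positivity named list of logical flag vectors (as returned by
#'   [callPositivity()]) for any of `edu`, `tunel`, `geminin`, `p63`;
#'   markers without a call become `NA`.
#' @param foci focus records (from [detectFoci()]) whose counts and areas
#'   fill `focusCount`/`focusAreas`; used for the focus-density channel
#'   (53BP1 in the reference pipeline).
#' @param rad51Foci optional second set of focus records whose per-nucleus
#'   counts fill `rad51Count` (for RECAP scoring).
#' @return data.frame, one row per nucleus: `label`, `areaUm2`, marker
#'   flags, `focusCount`, `focusAreas` (list column), `fociPerVolume`,
#'   `rad51Count`.
#' @export
buildCellTable <- function(nuclei, positivity = list(), foci = NULL,
                           rad51Foci = NULL) {
  stopifnot(is(nuclei, "NucleusTable"))
  df <- nuclei@nuclei
  cells <- data.frame(label = df$label, areaUm2 = df$areaUm2)
  for (m in c("edu", "tunel", "geminin", "p63")) {
    fl <- positivity[[m]]
    cells[[m]] <- if (is.null(fl)) NA else
      unname(fl[as.character(df$label)])
  }
  countOf <- function(fr) {
    if (is.null(fr) || nrow(fr) == 0L) return(integer(nrow(cells)))
    tb <- table(factor(fr$nucleusLabel, levels = df$label))
    as.integer(tb)
  }
  cells$focusCount <- countOf(foci)
  cells$focusAreas <- lapply(df$label, function(l)
    if (is.null(foci)) numeric(0) else foci$areaUm2[foci$nucleusLabel == l])
  cells$fociPerVolume <- if (nrow(cells))
    fociDensity(cells$focusCount, cells$areaUm2) else numeric(0)
  cells$rad51Count <- countOf(rad51Foci)
  cells
}

#' RECAP score: percent RAD51-focus-positive cells among geminin-positive
#'
#' A cell counts as RAD51-focus-positive when it carries at least `k` foci
#' (default 5). Only geminin-positive cells enter the numerator or the
#' denominator. When more than `sampleTarget` geminin-positive cells are
#' available (default 100, the "approximately 100 cells" scoring
#' convention), a seeded random subsample of exactly `sampleTarget` cells
#' is scored, without replacement; with `sampleTarget = Inf` the score is
#' deterministic and order-invariant.
#'
#' @param cells per-cell data.frame with columns `geminin` (logical) and
#'   a focus-count column.
#' @param k minimum focus count to call a cell positive (default 5).
#' @param sampleTarget number of geminin-positive cells to score.
#' @param seed integer seed for the subsample (required when subsampling
#'   triggers, for reproducibility).
#' @param countColumn which count column holds the RAD51 foci
#'   (default `"rad51Count"`; use `"focusCount"` for tables built from a
#'   single focus channel).
#' @return the score as a percentage in `[0, 100]`.
#' @examples
#' cells <- data.frame(geminin = TRUE, rad51Count = c(5, 4, 5, 0, 7))
#' recapScore(cells)  # 60
#' @export
recapScore <- function(cells, k = 5, sampleTarget = 100, seed = NULL,
                       countColumn = "rad51Count") {
  stopifnot(is.data.frame(cells), k >= 0)
  if (!countColumn %in% names(cells))
    stop("cells lacks focus-count column '", countColumn, "'")
  gem <- cells[!is.na(cells$geminin) & cells$geminin, , drop = FALSE]
  if (nrow(gem) == 0L)
    stop("RECAP score undefined: no geminin-positive cells to score")
  counts <- gem[[countColumn]]
  if (is.finite(sampleTarget) && nrow(gem) > sampleTarget) {
    if (is.null(seed))
      stop("subsampling ", sampleTarget, " of ", nrow(gem),
           " geminin-positive cells requires a seed for reproducibility")
    counts <- withLocalSeed(seed,
      counts[sample.int(length(counts), sampleTarget)])
  }
  100 * mean(counts >= k)
}

#' Summarize one field of view
#'
#' Positive fractions over the filtered cells, the RECAP inputs, and the
#' median and interquartile range of focus density and focus area (the
#' per-nucleus focus statistics are non-normal, so quartiles rather than
#' means are reported).
#'
#' @param cells per-cell data.frame from [buildCellTable()]; must be
#'   nonempty.
#' @param recapK focus-count threshold used for the RECAP input columns.
#' @return one-row data.frame: `nCells`, `fracEdu`, `fracTunel`,
#'   `fracGeminin`, `fracP63`, `nGemininPos`, `nGemininPosFociGEk`,
#'   `medianFociPerVol`, `iqrFociPerVol`, `medianFocusArea`,
#'   `iqrFocusArea`.
#' @export
summarizeFov <- function(cells, recapK = 5) {
  if (!is.data.frame(cells) || nrow(cells) == 0L)
    stop("cannot summarize an empty field: no cells after filtering")
  frac <- function(v) if (all(is.na(v))) NA_real_ else mean(v, na.rm = TRUE)
  gem <- !is.na(cells$geminin) & cells$geminin
  fa <- unlist(cells$focusAreas)
  data.frame(
    nCells = nrow(cells),
    fracEdu = frac(cells$edu),
    fracTunel = frac(cells$tunel),
    fracGeminin = frac(cells$geminin),
    fracP63 = frac(cells$p63),
    nGemininPos = sum(gem),
    nGemininPosFociGEk = sum(gem & cells$rad51Count >= recapK),
    medianFociPerVol = stats::median(cells$fociPerVolume),
    iqrFociPerVol = stats::IQR(cells$fociPerVolume),
    medianFocusArea = if (length(fa)) stats::median(fa) else NA_real_,
    iqrFocusArea = if (length(fa)) stats::IQR(fa) else NA_real_)
}
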