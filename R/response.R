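# Sample-level aggregation, radiosensitivity classification, the
# HR-proficiency call, and the statistical comparisons. Fields of view are
# the statistical unit for fraction comparisons (Student t); individual
# nuclei are the unit for focus comparisons (Kruskal-Wallis). p-values are
# reported unadjusted.

#' Aggregate per-field summaries to sample level
#'
#' Mean and standard error of the mean (SEM = sd / sqrt(nFov)) of each
#' positive fraction, per (sample, condition). SEM is reported as `NA`
#' when only one field is available.
#'
#' @param fov data.frame of per-field rows (from [summarizeFov()]) with
#'   `sampleId` and `condition` columns attached.
#' @return data.frame, one row per (sample, condition).
#' @export
summarizeSample <- function(fov) {
  stopifnot(all(c("sampleId", "condition") %in% names(fov)))
  groups <- split(fov, list(fov$sampleId, fov$condition), drop = TRUE)
  rows <- lapply(groups, function(g) {
    n <- nrow(g)
    sem <- function(v) if (n > 1) stats::sd(v) / sqrt(n) else NA_real_
    data.frame(
      sampleId = g$sampleId[1], condition = g$condition[1], nFov = n,
      meanFracEdu = mean(g$fracEdu), semFracEdu = sem(g$fracEdu),
      meanFracTunel = mean(g$fracTunel), semFracTunel = sem(g$fracTunel),
      meanFracGeminin = mean(g$fracGeminin),
      semFracGeminin = sem(g$fracGeminin),
      meanFracP63 = mean(g$fracP63), semFracP63 = sem(g$fracP63))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out[order(out$sampleId, out$condition), , drop = FALSE]
}

meanFracOf <- function(x, col) {
  if (is.data.frame(x)) {
    if (nrow(x) != 1L) stop("expected a single sample-condition row")
    x[[col]]
  } else if (is.numeric(x) && length(x) == 1L) x
  else stop("expected a one-row sample summary or a single number")
}

#' Relative proliferation: treated EdU fraction as percent of control
#'
#' @param treated,control one-row sample summaries (with `meanFracEdu`) or
#'   bare mean EdU-positive fractions.
#' @return percentage (100 = unchanged proliferation).
#' @examples
#' relativeProliferation(0.06, 0.12)  # 50
#' @export
relativeProliferation <- function(treated, control) {
  t <- meanFracOf(treated, "meanFracEdu")
  c <- meanFracOf(control, "meanFracEdu")
  if (!is.finite(c) || c <= 0)
    stop("relative proliferation undefined: control EdU fraction is ",
         "zero or missing")
  100 * t / c
}

#' Apoptosis ratio: treated over control TUNEL fraction
#'
#' @param treated,control one-row sample summaries (with `meanFracTunel`)
#'   or bare mean TUNEL-positive fractions.
#' @return nonnegative ratio (2 = twofold apoptosis induction).
#' @export
apoptosisRatio <- function(treated, control) {
  t <- meanFracOf(treated, "meanFracTunel")
  c <- meanFracOf(control, "meanFracTunel")
  if (!is.finite(c) || c <= 0)
    stop("apoptosis ratio undefined: control TUNEL fraction is zero or ",
         "missing")
  t / c
}

#' Classify radiosensitivity from relative proliferation
#'
#' Sensitive when relative proliferation drops below
#' `sensitiveThreshold` percent of the untreated level; resistant when at
#' least `resistantThreshold` percent is maintained; intermediate
#' otherwise. The default 30/60 boundaries are assay conventions, not
#' biology, and are configurable.
#'
#' @param rel relative proliferation in percent (vectorized, must be >= 0).
#' @param sensitiveThreshold percent below which a sample is sensitive.
#' @param resistantThreshold percent at or above which it is resistant.
#' @return factor with levels `sensitive`, `intermediate`, `resistant`.
#' @examples
#' classifyIrResponse(c(25, 45, 75))
#' @export
classifyIrResponse <- function(rel, sensitiveThreshold = 30,
                               resistantThreshold = 60) {
  if (any(!is.finite(rel)) || any(rel < 0))
    stop("relative proliferation must be nonnegative and finite")
  if (!(sensitiveThreshold >= 0 && sensitiveThreshold <= resistantThreshold
        && resistantThreshold <= 100))
    stop("thresholds must satisfy 0 <= sensitive <= resistant <= 100")
  cls <- ifelse(rel < sensitiveThreshold, "sensitive",
                ifelse(rel >= resistantThreshold, "resistant",
                       "intermediate"))
  factor(cls, levels = c("sensitive", "intermediate", "resistant"))
}

#' HR-proficiency call from the RECAP score
#'
#' Proficient when strictly more than `threshold` percent (default 50) of
#' geminin-positive cells formed at least the RECAP focus count.
#'
#' @param recapPercent RECAP score(s) in `[0, 100]`.
#' @param threshold percent boundary; proficiency requires `> threshold`.
#' @return logical: `TRUE` = HR-proficient.
#' @examples
#' hrCall(c(51, 50, 0))
#' @export
hrCall <- function(recapPercent, threshold = 50) {
  if (any(!is.finite(recapPercent)) || any(recapPercent < 0) ||
      any(recapPercent > 100))
    stop("RECAP score must lie in [0, 100]")
  recapPercent > threshold
}

#' Two-sided Student t comparison of per-field fractions
#'
#' Classic equal-variance Student t with `nA + nB - 2` degrees of freedom
#' (a Welch variant is available behind `welch = TRUE`).
#'
#' @param groupA,groupB numeric vectors of per-field values, each n >= 2.
#' @param welch use the unequal-variance Welch t instead.
#' @return list with `statistic`, `df`, `p.value`.
#' @export
compareFractions <- function(groupA, groupB, welch = FALSE) {
  if (length(groupA) < 2L || length(groupB) < 2L)
    stop("each group needs at least 2 fields of view")
  if (stats::sd(groupA) == 0 && stats::sd(groupB) == 0 &&
      mean(groupA) == mean(groupB))
    return(list(statistic = 0, df = length(groupA) + length(groupB) - 2,
                p.value = 1))
  tt <- stats::t.test(groupA, groupB, var.equal = !welch)
  list(statistic = unname(tt$statistic), df = unname(tt$parameter),
       p.value = tt$p.value)
}

#' Kruskal-Wallis comparison of per-nucleus focus statistics
#'
#' Rank-based H with tie correction; p from the chi-square distribution
#' with `length(groups) - 1` degrees of freedom. Invariant under any
#' strictly monotone transform of the pooled values.
#'
#' @param groups list of >= 2 numeric vectors (per-nucleus focus densities
#'   or focus areas), each nonempty, total length >= 3.
#' @return list with `statistic` (H), `df`, `p.value`.
#' @export
compareFoci <- function(groups) {
  if (!is.list(groups) || length(groups) < 2L)
    stop("need at least two groups")
  if (any(vapply(groups, length, 1L) == 0L))
    stop("every group must be nonempty")
  if (sum(lengths(groups)) < 3L)
    stop("need at least 3 values in total")
  values <- unlist(groups)
  g <- factor(rep(seq_along(groups), lengths(groups)))
  if (length(unique(values)) == 1L)
    return(list(statistic = 0, df = length(groups) - 1L, p.value = 1))
  kw <- stats::kruskal.test(values, g)
  list(statistic = unname(kw$statistic), df = unname(kw$parameter),
       p.value = kw$p.value)
}
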