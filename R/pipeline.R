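# Config-driven orchestration: manifest -> per-FoV analysis -> per-sample
# aggregation, classification, statistics and report files.

#' Build a pipeline run configuration
#'
#' All protocol constants live here and are echoed verbatim into every
#' report: the 10 um^2 minimum nucleus area, the RECAP focus threshold
#' (>= 5 foci) and sampling target (~100 geminin-positive cells), the
#' 30%/60% relative-proliferation class boundaries, the 50% RECAP
#' HR-proficiency boundary, the 5 Gy classification dose and the
#' 3.3/16.5/33 uM cisplatin series.
#'
#' @param manifest path to the manifest CSV.
#' @param outputDir directory for report files.
#' @param channelRoles named character vector mapping roles (`nuclear`,
#'   `edu`, `tunel`, `geminin`, `rad51`, `p63`, `foci`) to channel labels;
#'   set a role to `NA` to skip that readout.
#' @param minAreaUm2 minimum nucleus area in um^2 (strictly smaller
#'   nuclei are excluded).
#' @param recapK minimum RAD51 focus count for a RECAP-positive cell.
#' @param recapSampleTarget geminin-positive cells scored per sample.
#' @param sensitiveThreshold,resistantThreshold relative-proliferation
#'   class boundaries in percent.
#' @param hrThreshold RECAP percent above which a sample is HR-proficient.
#' @param gamma gamma-correction exponent applied to the nuclear channel
#'   before segmentation.
#' @param positivityRule `"otsu"` or `"absolute"` (see [callPositivity()]).
#' @param positivityThreshold absolute threshold (counts), used when
#'   `positivityRule = "absolute"`.
#' @param fociGate `"p63"` restricts focus counting to p63-positive nuclei;
#'   `"all"` counts in every retained nucleus.
#' @param controlCondition condition id of the untreated reference.
#' @param classificationDose condition at which the sensitivity class is
#'   assigned (default `"5Gy"`).
#' @param cisplatinSeriesUM the cisplatin concentration series (uM) the
#'   default experiment design uses.
#' @param nucleusRadiusUm expected nucleus radius passed to
#'   [segmentNuclei()].
#' @param seed seed for the seeded stages (RECAP subsampling).
#' @param welch use Welch instead of Student t for fraction comparisons.
#' @return a validated `RunConfig` (a classed list).
#' @export
runConfig <- function(manifest, outputDir,
                      channelRoles = c(nuclear = "DAPI", edu = "EdU",
                                       tunel = "TUNEL", geminin = "geminin",
                                       rad51 = "RAD51", p63 = "p63",
                                       foci = "53BP1"),
                      minAreaUm2 = 10, recapK = 5, recapSampleTarget = 100,
                      sensitiveThreshold = 30, resistantThreshold = 60,
                      hrThreshold = 50, gamma = 0.7,
                      positivityRule = c("otsu", "absolute"),
                      positivityThreshold = NA_real_,
                      fociGate = c("p63", "all"),
                      controlCondition = "untreated",
                      classificationDose = "5Gy",
                      cisplatinSeriesUM = c(3.3, 16.5, 33),
                      nucleusRadiusUm = 4, seed = 1L, welch = FALSE) {
  cfg <- list(manifest = manifest, outputDir = outputDir,
              channelRoles = channelRoles, minAreaUm2 = minAreaUm2,
              recapK = recapK, recapSampleTarget = recapSampleTarget,
              sensitiveThreshold = sensitiveThreshold,
              resistantThreshold = resistantThreshold,
              hrThreshold = hrThreshold, gamma = gamma,
              positivityRule = match.arg(positivityRule),
              positivityThreshold = positivityThreshold,
              fociGate = match.arg(fociGate),
              controlCondition = controlCondition,
              classificationDose = classificationDose,
              cisplatinSeriesUM = cisplatinSeriesUM,
              nucleusRadiusUm = nucleusRadiusUm,
              seed = as.integer(seed), welch = welch)
  validateRunConfig(cfg)
  class(cfg) <- c("RunConfig", "list")
  cfg
}

validateRunConfig <- function(cfg) {
  with(cfg, {
    if (!(sensitiveThreshold >= 0 &&
          sensitiveThreshold <= resistantThreshold &&
          resistantThreshold <= 100))
      stop("need 0 <= sensitiveThreshold <= resistantThreshold <= 100")
    if (recapK < 0) stop("recapK must be >= 0")
    if (minAreaUm2 < 0) stop("minAreaUm2 must be >= 0")
    if (gamma <= 0) stop("gamma must be > 0")
  })
  invisible(cfg)
}

#' Read a run configuration from a YAML file
#'
#' Unknown keys are an error (listed by name), so typos never silently
#' fall back to defaults.
#'
#' @param path YAML file whose keys mirror [runConfig()] arguments.
#' @return a `RunConfig`.
#' @export
readRunConfig <- function(path) {
  vals <- yaml::read_yaml(path)
  known <- names(formals(runConfig))
  unknown <- setdiff(names(vals), known)
  if (length(unknown))
    stop("unknown config keys: ", paste(unknown, collapse = ", "))
  if (!is.null(vals$channelRoles))
    vals$channelRoles <- unlist(vals$channelRoles)
  do.call(runConfig, vals)
}

# analysis of a single field of view; returns cells + summary + exclusions
analyzeFov <- function(image, cfg, truthFlags = NULL) {
  roles <- cfg$channelRoles
  img <- image
  fociCh <- roles[["foci"]]
  if (!is.na(fociCh) && fociCh %in% img@channels &&
      length(dim(img@pixels[[fociCh]])) == 3L)
    img@pixels[[fociCh]] <- maxProject(img@pixels[[fociCh]])
  nuc <- roles[["nuclear"]]
  img@pixels[[nuc]] <- gammaCorrect(img@pixels[[nuc]], cfg$gamma)
  nt <- segmentNuclei(img, channel = nuc,
                      nucleusRadiusUm = cfg$nucleusRadiusUm)
  nt <- filterNuclei(nt, cfg$minAreaUm2)

  pos <- list()
  for (m in c("edu", "tunel", "geminin", "p63")) {
    ch <- roles[[m]]
    if (is.na(ch) || !ch %in% img@channels) next
    pos[[m]] <- if (nrow(nt@nuclei) >= 2L)
      callPositivity(nt, ch, rule = cfg$positivityRule,
                     threshold = cfg$positivityThreshold)
    else stats::setNames(logical(nrow(nt@nuclei)),
                         nt@nuclei$label)
  }

  gated <- nt
  if (cfg$fociGate == "p63" && !is.null(pos$p63)) {
    keep <- nt@nuclei$label[unname(pos$p63)]
    gatedLab <- nt@labelImage
    gatedLab[!(gatedLab %in% c(0L, keep))] <- 0L
    gated <- new("NucleusTable", labelImage = gatedLab,
                 nuclei = nt@nuclei[nt@nuclei$label %in% keep, ,
                                    drop = FALSE],
                 umPerPx = nt@umPerPx, excluded = nt@excluded)
  }
  foci <- if (!is.na(fociCh) && fociCh %in% img@channels)
    detectFoci(img, fociCh, gated) else NULL
  radCh <- roles[["rad51"]]
  radFoci <- if (!is.na(radCh) && radCh %in% img@channels)
    detectFoci(img, radCh, nt) else NULL

  cells <- buildCellTable(nt, pos, foci = foci, rad51Foci = radFoci)
  # focus density is defined on the gated population only
  if (cfg$fociGate == "p63" && !is.null(pos$p63))
    cells$inFociGate <- unname(pos$p63)
  else cells$inFociGate <- rep(TRUE, nrow(cells))
  list(nuclei = nt, cells = cells,
       summary = if (nrow(cells)) summarizeFov(cells, cfg$recapK) else NULL,
       excluded = nt@excluded,
       fociOutside = if (is.null(foci)) 0L else
         attr(foci, "outsideCount", exact = TRUE) %||% 0L)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Run the full pipeline over a manifest
#'
#' For every field: read, maximum-project the focus stack, gamma-correct
#' the nuclear channel, segment, filter, detect foci, and score. Then
#' aggregate per sample, classify the treatment response against the
#' control condition, run the statistical comparisons, and write the
#' report files (`fov.csv`, `samples.csv`, `response.csv`, `cells.csv`,
#' `exclusions.csv`, and the full configuration as `config.yaml`).
#' A field that fails is recorded in `failures.csv` and the run continues.
#' Deterministic for a fixed config (including `seed`).
#'
#' @param cfg a `RunConfig` from [runConfig()] / [readRunConfig()].
#' @return invisibly, a list with the report tables (`fov`, `samples`,
#'   `response`, `failures`) and the output paths.
#' @export
runPipeline <- function(cfg) {
  stopifnot(inherits(cfg, "RunConfig"))
  manifest <- utils::read.csv(cfg$manifest, check.names = FALSE)
  dir.create(cfg$outputDir, recursive = TRUE, showWarnings = FALSE)
  baseDir <- dirname(cfg$manifest)

  fovRows <- list(); cellRows <- list(); failures <- list()
  exclTotal <- c(border = 0L, smallArea = 0L, fociOutsideNuclei = 0L)
  for (i in seq_len(nrow(manifest))) {
    row <- manifest[i, , drop = FALSE]
    res <- tryCatch({
      img <- readCalibratedImage(file.path(baseDir, row$file), row)
      analyzeFov(img, cfg)
    }, error = function(e) e)
    if (inherits(res, "error")) {
      failures[[length(failures) + 1L]] <- data.frame(
        file = row$file, error = conditionMessage(res))
      next
    }
    if (is.null(res$summary)) {
      failures[[length(failures) + 1L]] <- data.frame(
        file = row$file, error = "no nuclei retained after filtering")
      next
    }
    exclTotal <- exclTotal +
      c(res$excluded, fociOutsideNuclei = as.integer(res$fociOutside))
    s <- cbind(data.frame(sampleId = row$sample_id,
                          condition = row$condition,
                          fovIndex = row$fov_index, file = row$file),
               res$summary)
    fovRows[[length(fovRows) + 1L]] <- s
    cells <- res$cells
    cells$focusAreas <- vapply(cells$focusAreas, function(a)
      paste(signif(a, 6), collapse = ";"), "")
    cellRows[[length(cellRows) + 1L]] <-
      cbind(data.frame(sampleId = row$sample_id, condition = row$condition,
                       fovIndex = row$fov_index), cells)
  }
  if (!length(fovRows))
    stop("no field of view could be analyzed; see failures")
  fov <- do.call(rbind, fovRows)
  cellsAll <- do.call(rbind, cellRows)
  samples <- summarizeSample(fov)

  response <- buildResponseTable(fov, cellsAll, samples, cfg)

  failDf <- if (length(failures)) do.call(rbind, failures) else
    data.frame(file = character(0), error = character(0))
  wp <- function(df, name) {
    p <- file.path(cfg$outputDir, name)
    utils::write.csv(df, p, row.names = FALSE)
    p
  }
  paths <- c(fov = wp(fov, "fov.csv"), samples = wp(samples, "samples.csv"),
             response = wp(response, "response.csv"),
             cells = wp(cellsAll, "cells.csv"),
             failures = wp(failDf, "failures.csv"),
             exclusions = wp(data.frame(stage = names(exclTotal),
                                        nExcluded = as.integer(exclTotal)),
                             "exclusions.csv"))
  cfgOut <- cfg; class(cfgOut) <- "list"
  cfgOut$channelRoles <- as.list(cfgOut$channelRoles)
  yaml::write_yaml(cfgOut, file.path(cfg$outputDir, "config.yaml"))
  invisible(list(fov = fov, samples = samples, response = response,
                 cells = cellsAll, failures = failDf, paths = paths,
                 excluded = exclTotal))
}

# per (sample, condition != control): relative proliferation, class,
# apoptosis ratio, RECAP/HR call, t-tests on per-FoV fractions, KW on
# per-nucleus focus densities
buildResponseTable <- function(fov, cells, samples, cfg) {
  rows <- list()
  for (sid in unique(samples$sampleId)) {
    ss <- samples[samples$sampleId == sid, , drop = FALSE]
    ctrl <- ss[ss$condition == cfg$controlCondition, , drop = FALSE]
    for (cond in setdiff(ss$condition, cfg$controlCondition)) {
      tr <- ss[ss$condition == cond, , drop = FALSE]
      rel <- if (nrow(ctrl) == 1L && is.finite(ctrl$meanFracEdu) &&
                 ctrl$meanFracEdu > 0)
        relativeProliferation(tr, ctrl) else NA_real_
      irClass <- if (is.finite(rel))
        as.character(classifyIrResponse(rel, cfg$sensitiveThreshold,
                                        cfg$resistantThreshold))
      else NA_character_
      apo <- if (nrow(ctrl) == 1L && is.finite(ctrl$meanFracTunel) &&
                 ctrl$meanFracTunel > 0)
        apoptosisRatio(tr, ctrl) else NA_real_

      cellsT <- cells[cells$sampleId == sid & cells$condition == cond, ,
                      drop = FALSE]
      recap <- tryCatch(
        recapScore(cellsT, k = cfg$recapK,
                   sampleTarget = cfg$recapSampleTarget, seed = cfg$seed),
        error = function(e) NA_real_)
      hr <- if (is.finite(recap)) hrCall(recap, cfg$hrThreshold) else NA

      fovT <- fov[fov$sampleId == sid & fov$condition == cond, ]
      fovC <- fov[fov$sampleId == sid &
                  fov$condition == cfg$controlCondition, ]
      tEdu <- tTun <- list(statistic = NA_real_, p.value = NA_real_)
      if (nrow(fovT) >= 2L && nrow(fovC) >= 2L) {
        tEdu <- compareFractions(fovT$fracEdu, fovC$fracEdu,
                                 welch = cfg$welch)
        tTun <- compareFractions(fovT$fracTunel, fovC$fracTunel,
                                 welch = cfg$welch)
      }
      cellsC <- cells[cells$sampleId == sid &
                      cells$condition == cfg$controlCondition, ,
                      drop = FALSE]
      kw <- list(statistic = NA_real_, p.value = NA_real_)
      dT <- cellsT$fociPerVolume[cellsT$inFociGate]
      dC <- cellsC$fociPerVolume[cellsC$inFociGate]
      if (length(dT) > 0L && length(dC) > 0L &&
          length(dT) + length(dC) >= 3L)
        kw <- compareFoci(list(treated = dT, control = dC))

      rows[[length(rows) + 1L]] <- data.frame(
        sampleId = sid, condition = cond,
        controlCondition = cfg$controlCondition,
        atClassificationDose = identical(cond, cfg$classificationDose),
        relativeProliferation = rel, irClass = irClass,
        apoptosisRatio = apo, recapPercent = recap, hrProficient = hr,
        tStatEdu = tEdu$statistic, pEdu = tEdu$p.value,
        tStatTunel = tTun$statistic, pTunel = tTun$p.value,
        kwStatFoci = kw$statistic, pFoci = kw$p.value,
        sensitiveThreshold = cfg$sensitiveThreshold,
        resistantThreshold = cfg$resistantThreshold,
        hrThreshold = cfg$hrThreshold)
    }
  }
  if (!length(rows))
    return(data.frame(sampleId = character(0), condition = character(0)))
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Generate a synthetic experiment and return its manifest path
#'
#' Thin wrapper over [generateExperiment()] for the command-line entry
#' point; prints and returns the manifest path.
#'
#' @param scenario a [SliceScenario-class] (default study conditions).
#' @param design data.frame of `condition`, `nFov`.
#' @param outDir output directory.
#' @param ... passed to [generateExperiment()].
#' @return the manifest path, invisibly.
#' @export
simulateExperiment <- function(scenario = sliceScenario(),
                               design = data.frame(
                                 condition = c("untreated", "5Gy"),
                                 nFov = c(5L, 5L)),
                               outDir, ...) {
  res <- generateExperiment(scenario, design, outDir, ...)
  message("manifest written to ", res$manifest)
  invisible(res$manifest)
}
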