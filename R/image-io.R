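# Calibrated multichannel TIFF I/O and the stated pre-processing steps:
# maximum projection of the focus z-stack and gamma correction of the
# nuclear channel. Pixel values are 16-bit camera counts throughout; the
# manifest is the authoritative source of calibration and channel order.

# encode/decode the manifest channel_list field ("DAPI;...;53BP1:3")
parseChannelList <- function(channelList) {
  parts <- strsplit(channelList, ";", fixed = TRUE)[[1]]
  spl <- strsplit(parts, ":", fixed = TRUE)
  data.frame(channel = vapply(spl, `[`, "", 1L),
             planes = vapply(spl, function(x)
               if (length(x) > 1L) as.integer(x[2]) else 1L, 1L))
}

#' Write a CalibratedImage as a 16-bit multipage TIFF
#'
#' One page per 2D channel; z-stack channels contribute one page per plane,
#' bottom to top. Values must be integer counts in `[0, 65535]`.
#'
#' @param image a [CalibratedImage-class].
#' @param path output file path.
#' @return invisibly, `path`.
#' @export
writeCalibratedImage <- function(image, path) {
  stopifnot(is(image, "CalibratedImage"))
  pages <- list()
  for (ch in image@channels) {
    a <- image@pixels[[ch]]
    if (length(dim(a)) == 3L) {
      for (p in seq_len(dim(a)[3])) pages[[length(pages) + 1L]] <- a[, , p]
    } else pages[[length(pages) + 1L]] <- a
  }
  pages <- lapply(pages, function(m) {
    if (any(m < 0 | m > 65535))
      stop("pixel values outside the 16-bit range [0, 65535]")
    matrix(as.numeric(m) / 65535, nrow = nrow(m))
  })
  tiff::writeTIFF(pages, path, bits.per.sample = 16L, compression = "LZW")
  invisible(path)
}

#' Read one field of view as described by its manifest row
#'
#' The manifest is authoritative for both the channel layout and the pixel
#' calibration: the TIFF page count must match the manifest `channel_list`,
#' and `um_per_px` must be present (there is no silent default). If the file
#' itself carries resolution tags that disagree with the manifest by more
#' than 1%, a warning is raised and the manifest value wins.
#'
#' @param path path to the TIFF (used as-is; resolve manifest-relative paths
#'   before calling).
#' @param manifestRow one-row data.frame with at least `um_per_px` and
#'   `channel_list` (as written by [generateExperiment()]).
#' @param zStepUm z spacing assigned to any stacked channel (um); the
#'   manifest format does not carry it, default 1.
#' @return a [CalibratedImage-class] with integer counts.
#' @export
readCalibratedImage <- function(path, manifestRow, zStepUm = 1) {
  if (!file.exists(path)) stop("image file not found: ", path)
  um <- suppressWarnings(as.numeric(manifestRow$um_per_px))
  if (length(um) != 1L || !is.finite(um) || um <= 0)
    stop("manifest row carries no usable um_per_px calibration for ", path,
         "; calibration is required, never defaulted")
  layout <- parseChannelList(as.character(manifestRow$channel_list))
  pages <- tryCatch(tiff::readTIFF(path, all = TRUE, info = TRUE),
                    error = function(e)
                      stop("failed to read TIFF ", path, ": ",
                           conditionMessage(e)))
  nExpected <- sum(layout$planes)
  if (length(pages) != nExpected)
    stop(sprintf("page/channel mismatch in %s: %d pages in file, %d implied by channel_list '%s'",
                 path, length(pages), nExpected, manifestRow$channel_list))
  xres <- attr(pages[[1]], "x.resolution")
  unit <- attr(pages[[1]], "resolution.unit")
  if (!is.null(xres) && is.numeric(xres) && xres > 0 && !is.null(unit)) {
    umPerUnit <- switch(unit, inch = 25400, cm = 10000, NA_real_)
    if (is.finite(umPerUnit)) {
      umFile <- umPerUnit / xres
      if (abs(umFile - um) / um > 0.01)
        warning(sprintf(
          "calibration mismatch for %s: manifest %.4g um/px vs file tags %.4g um/px; using the manifest",
          path, um, umFile))
    }
  }
  toCounts <- function(m) matrix(as.integer(round(m * 65535)), nrow = nrow(m))
  px <- list(); i <- 0L
  for (r in seq_len(nrow(layout))) {
    np <- layout$planes[r]
    if (np == 1L) {
      i <- i + 1L
      px[[layout$channel[r]]] <- toCounts(pages[[i]])
    } else {
      planes <- lapply(seq_len(np), function(p) toCounts(pages[[i + p]]))
      i <- i + np
      px[[layout$channel[r]]] <- array(unlist(planes),
                                       dim = c(dim(planes[[1]]), np))
    }
  }
  CalibratedImage(px, umPerPx = um,
                  zStepUm = if (any(layout$planes > 1L)) zStepUm
                            else NA_real_)
}

#' Maximum-intensity projection of a focus z-stack
#'
#' Per-pixel maximum across planes. 2D input is returned unchanged
#' (projection is idempotent); a 3D array with a single plane is returned
#' with a warning. Storage mode (integer counts) is preserved.
#'
#' @param stack a 2D matrix or a y-by-x-by-plane array.
#' @return a 2D matrix.
#' @examples
#' maxProject(array(c(0, 5, 3), dim = c(1, 1, 3)))
#' @export
maxProject <- function(stack) {
  d <- dim(stack)
  if (length(d) == 2L) return(stack)
  if (length(d) != 3L) stop("stack must be 2D or 3D")
  if (d[3] == 1L) {
    warning("single-plane stack: maximum projection is the identity")
    return(stack[, , 1])
  }
  out <- stack[, , 1]
  for (p in 2:d[3]) out <- pmax(out, stack[, , p])
  if (is.integer(stack)) storage.mode(out) <- "integer"
  out
}

#' Gamma correction on a fixed normalization maximum
#'
#' Computes `maxVal * (x / maxVal) ^ gamma`. The normalization maximum is
#' the dtype maximum (65535) for integer count images and the observed
#' maximum for float images, keeping the transform dtype-stable; it can be
#' overridden. The transform is monotone in the input for any `gamma > 0`.
#'
#' @param image 2D numeric matrix.
#' @param gamma positive exponent; values < 1 brighten dim structures.
#' @param maxVal normalization maximum; default as described.
#' @return matrix of the same shape and storage mode.
#' @examples
#' gammaCorrect(matrix(65535 / 4, 2, 2), gamma = 0.5)  # -> 65535/2
#' @export
gammaCorrect <- function(image, gamma, maxVal = NULL) {
  if (!is.numeric(gamma) || length(gamma) != 1L || !is.finite(gamma) ||
      gamma <= 0)
    stop("gamma must be a single positive number")
  if (is.null(maxVal))
    maxVal <- if (is.integer(image)) 65535 else max(image, 1e-12)
  out <- maxVal * (pmax(image, 0) / maxVal)^gamma
  if (is.integer(image)) {
    out <- round(out)
    storage.mode(out) <- "integer"
  }
  out
}
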