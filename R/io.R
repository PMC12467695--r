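# Frame / sequence / results I/O.  Two image containers only (8-bit
# grayscale PNG and TIFF, multi-page TIFF for sequences); sequences carry a
# JSON ground-truth sidecar; results are JSON (full fidelity) or CSV
# (flattened per-frame rows).  All readers and writers round-trip
# losslessly at the stated precision.

RESULTS_SCHEMA_VERSION <- "1.0"

#' Default run configuration
#'
#' A single nested list holding every tunable of the pipeline, fully
#' serializable to YAML; CLI flags override config values and the
#' effective config is embedded verbatim in result files for provenance.
#'
#' @param ... named overrides of the top-level sections (synth, detect,
#'   measure, gates, stats, seed).
#' @return nested named list.
#' @export
grafConfig <- function(...) {
  cfg <- list(
    synth = list(alpha = 70, inclination = 0, nFrames = 1,
      imageShape = c(256L, 256L), speckleScale = 0.2, blurSigma = 1.0,
      shadowAttenuation = 0.3, backgroundLevel = 20, boneIntensity = 220,
      rotationPerFrame = 0, translationPerFrame = c(0, 0),
      offplaneFrames = integer(0)),
    detect = defaultDetectParams(),
    measure = defaultMeasureParams(),
    gates = qualityGates(),
    stats = list(z = 1.96, iccType = "single"),
    seed = 1L)
  utils::modifyList(cfg, list(...))
}

#' Read a run configuration from YAML
#'
#' @param path YAML file; missing keys fall back to \code{\link{grafConfig}}
#'   defaults.
#' @return nested named list.
#' @export
readGrafConfig <- function(path) {
  utils::modifyList(grafConfig(), yaml::read_yaml(path))
}

#' Write a run configuration to YAML
#'
#' @param config nested named list.
#' @param path output file.
#' @return \code{path}, invisibly.
#' @export
writeGrafConfig <- function(config, path) {
  yaml::write_yaml(config, path)
  invisible(path)
}

frameSidecarPath <- function(path) paste0(path, ".json")

#' Read a single frame (PNG or TIFF)
#'
#' Accepts single-channel 8-bit images (16-bit accepted and linearly
#' rescaled to [0, 255]).  RGB input is rejected with guidance to convert.
#' Pixel spacing is taken from a \code{<path>.json} sidecar when present;
#' otherwise the documented default of 0.1 mm/px is recorded with a
#' notice.
#'
#' @param path image file.
#' @return an \linkS4class{UltrasoundFrame}.
#' @export
readFrame <- function(path) {
  if (!file.exists(path)) stop("readFrame: no such file: ", path)
  img <- EBImage::readImage(path)
  if (EBImage::colorMode(img) != EBImage::Grayscale ||
      length(dim(img)) > 2L && dim(img)[3] > 1L)
    stop("readFrame: ", path, " is not single-channel grayscale; ",
         "convert it to 8-bit grayscale first")
  m <- t(EBImage::imageData(img)) * 255    # EBImage stores (x, y)
  spacing <- 0.1
  sidecar <- frameSidecarPath(path)
  if (file.exists(sidecar)) {
    meta <- jsonlite::read_json(sidecar, simplifyVector = TRUE)
    if (!is.null(meta$pixelSpacing)) spacing <- meta$pixelSpacing
  } else {
    message("readFrame: no sidecar for ", basename(path),
            "; using default pixel spacing 0.1 mm/px")
  }
  new("UltrasoundFrame", data = round(pmin(pmax(m, 0), 255), 6),
      pixelSpacing = spacing)
}

#' Write a single frame as 8-bit grayscale PNG or TIFF
#'
#' @param frame an \linkS4class{UltrasoundFrame}.
#' @param path output file (.png or .tif/.tiff).
#' @param sidecar write a \code{<path>.json} metadata sidecar with the
#'   pixel spacing (default TRUE).
#' @return \code{path}, invisibly.
#' @export
writeFrame <- function(frame, path, sidecar = TRUE) {
  stopifnot(is(frame, "UltrasoundFrame"))
  img <- EBImage::Image(t(frame@data) / 255, colormode = "Grayscale")
  EBImage::writeImage(img, path, bits.per.sample = 8L)
  if (sidecar)
    jsonlite::write_json(
      list(pixelSpacing = frame@pixelSpacing, bitDepth = 8L),
      frameSidecarPath(path), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a frame sequence
#'
#' \code{path} is either a directory of frames (read in lexicographic
#' order) or a multi-page TIFF (read in page order).  All frames must
#' share one shape.  A \code{ground_truth.json} sidecar next to the frames
#' supplies the pixel spacing when present.
#'
#' @param path directory or multi-page TIFF.
#' @return list of \linkS4class{UltrasoundFrame}.
#' @export
readSequence <- function(path) {
  if (dir.exists(path)) {
    files <- sort(list.files(path, pattern = "\\.(png|tif|tiff)$",
                             ignore.case = TRUE, full.names = TRUE))
    if (!length(files)) stop("readSequence: no frames in ", path)
    frames <- lapply(files, function(f) suppressMessages(readFrame(f)))
    sidecar <- file.path(path, "ground_truth.json")
    if (file.exists(sidecar)) {
      meta <- jsonlite::read_json(sidecar, simplifyVector = TRUE)
      if (!is.null(meta$pixelSpacing))
        frames <- lapply(frames, function(fr) {
          fr@pixelSpacing <- meta$pixelSpacing; fr
        })
    }
  } else {
    img <- EBImage::readImage(path)
    d <- dim(img)
    nf <- if (length(d) == 2L) 1L else d[3]
    dat <- EBImage::imageData(img)
    frames <- lapply(seq_len(nf), function(k) {
      m <- if (length(d) == 2L) t(dat) else t(dat[, , k])
      new("UltrasoundFrame", data = round(pmin(pmax(m * 255, 0), 255), 6))
    })
  }
  shapes <- vapply(frames, function(f) paste(dim(f@data), collapse = "x"),
                   character(1))
  if (length(unique(shapes)) > 1L)
    stop("readSequence: mixed frame shapes within the sequence")
  frames
}

#' Write a frame sequence with its ground-truth sidecar
#'
#' Writes frames as zero-padded PNGs (\code{frame_0001.png}, ...) into a
#' directory, or as one multi-page TIFF when \code{path} ends in
#' .tif/.tiff, plus a \code{ground_truth.json} sidecar (schema documented
#' in the JSON itself via \code{schemaVersion}).
#'
#' @param frames list of \linkS4class{UltrasoundFrame}.
#' @param path output directory or .tif path.
#' @param truths optional list of \linkS4class{GroundTruth}.
#' @return \code{path}, invisibly.
#' @export
writeSequence <- function(frames, path, truths = NULL) {
  isTiff <- grepl("\\.tiff?$", path, ignore.case = TRUE)
  if (isTiff) {
    arr <- vapply(frames, function(f) t(f@data) / 255,
                  matrix(0, ncol(frames[[1]]@data), nrow(frames[[1]]@data)))
    EBImage::writeImage(EBImage::Image(arr, colormode = "Grayscale"), path,
                        bits.per.sample = 8L)
    sidecar <- paste0(path, ".json")
  } else {
    dir.create(path, showWarnings = FALSE, recursive = TRUE)
    for (k in seq_along(frames))
      writeFrame(frames[[k]],
                 file.path(path, sprintf("frame_%04d.png", k)),
                 sidecar = FALSE)
    sidecar <- file.path(path, "ground_truth.json")
  }
  meta <- list(schemaVersion = RESULTS_SCHEMA_VERSION,
               nFrames = length(frames),
               pixelSpacing = frames[[1]]@pixelSpacing)
  if (!is.null(truths)) meta$frames <- lapply(truths, resultToList)
  jsonlite::write_json(meta, sidecar, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Convert a result object to a plain list (for JSON serialization)
#'
#' @param object any package result object.
#' @return a named list of plain vectors.
#' @export
setGeneric("resultToList", function(object) standardGeneric("resultToList"))

#' @rdname resultToList
setMethod("resultToList", "LineModel", function(object) {
  list(theta = object@theta, offset = object@offset,
       rmsResidual = object@rmsResidual, nPoints = object@nPoints)
})

#' @rdname resultToList
setMethod("resultToList", "LandmarkDetection", function(object) {
  list(label = object@label, box = object@box,
       confidence = object@confidence)
})

#' @rdname resultToList
setMethod("resultToList", "GroundTruth", function(object) {
  list(frameIndex = object@frameIndex, alphaTrue = object@alphaTrue,
       inclinationTrue = object@inclinationTrue,
       rimPoint = object@rimPoint, lowerLimbPoint = object@lowerLimbPoint,
       rimBox = object@rimBox, lowerLimbBox = object@lowerLimbBox,
       diagnosticQuality = object@diagnosticQuality)
})

#' @rdname resultToList
setMethod("resultToList", "AlphaMeasurement", function(object) {
  out <- list(status = object@status, method = object@method,
              frameIndex = object@frameIndex, alphaDeg = object@alphaDeg,
              inclinationDeg = object@inclinationDeg)
  if (!is.null(object@baseline)) {
    out$baseline <- resultToList(object@baseline)
    out$roofLine <- resultToList(object@roofLine)
    out$iliacLine <- resultToList(object@iliacLine)
  }
  out
})

#' @rdname resultToList
setMethod("resultToList", "FrameQualityReport", function(object) {
  list(frameIndex = object@frameIndex, rimDetected = object@rimDetected,
       lowerLimbDetected = object@lowerLimbDetected,
       rimConfidence = object@rimConfidence,
       lowerLimbConfidence = object@lowerLimbConfidence,
       inclinationDeg = object@inclinationDeg, iliacRms = object@iliacRms,
       roofRms = object@roofRms, isDiagnostic = object@isDiagnostic,
       rejectReasons = as.list(object@rejectReasons))
})

#' @rdname resultToList
setMethod("resultToList", "SequenceResult", function(object) {
  list(nFrames = length(object@measurements),
       nDiagnostic = object@nDiagnostic,
       diagnosticFrames = object@diagnosticFrames,
       alphaMean = object@alphaMean, alphaSd = object@alphaSd,
       measurements = lapply(object@measurements, resultToList),
       reports = lapply(object@reports, resultToList))
})

#' @rdname resultToList
setMethod("resultToList", "AgreementStats", function(object) {
  list(bias = object@bias, sdDiff = object@sdDiff,
       loaLower = object@loaLower, loaUpper = object@loaUpper,
       n = object@n, z = object@z)
})

#' @rdname resultToList
setMethod("resultToList", "ICCResult", function(object) {
  list(icc = object@icc, ciLower = object@ciLower,
       ciUpper = object@ciUpper, model = object@model,
       nSubjects = object@nSubjects, nRaters = object@nRaters,
       meanSquares = as.list(object@meanSquares))
})

#' @rdname resultToList
setMethod("resultToList", "AnovaResult", function(object) {
  list(fStat = object@fStat, pValue = object@pValue, eta2 = object@eta2,
       cohensF = object@cohensF, power = object@power,
       groupNs = object@groupNs, df = object@df,
       sumSquares = as.list(object@sumSquares))
})

#' Flatten a SequenceResult to a per-frame data frame
#'
#' @param result a \linkS4class{SequenceResult}.
#' @return data.frame with one row per frame.
#' @export
sequenceFrameTable <- function(result) {
  stopifnot(is(result, "SequenceResult"))
  rows <- lapply(seq_along(result@measurements), function(k) {
    m <- result@measurements[[k]]
    r <- result@reports[[k]]
    data.frame(frame = k, status = m@status, alphaDeg = m@alphaDeg,
      inclinationDeg = m@inclinationDeg, rimConfidence = r@rimConfidence,
      lowerLimbConfidence = r@lowerLimbConfidence, iliacRms = r@iliacRms,
      roofRms = r@roofRms, isDiagnostic = r@isDiagnostic,
      rejectReasons = paste(r@rejectReasons, collapse = ";"))
  })
  do.call(rbind, rows)
}

#' Write a result object to JSON or CSV
#'
#' JSON keeps full float fidelity and embeds the schema version plus, when
#' supplied, the effective run configuration.  CSV flattens a
#' \linkS4class{SequenceResult} to per-frame rows (other result types are
#' written as a single-row table of their scalar fields).
#'
#' @param result a package result object.
#' @param path output file.
#' @param format "json" or "csv".
#' @param config optional run configuration to embed (JSON only).
#' @return \code{path}, invisibly.
#' @export
writeResults <- function(result, path, format = c("json", "csv"),
                         config = NULL) {
  format <- match.arg(format)
  if (format == "json") {
    payload <- list(schemaVersion = RESULTS_SCHEMA_VERSION,
                    resultClass = class(result)[1],
                    result = resultToList(result))
    if (!is.null(config)) payload$config <- config
    jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                         null = "null")
  } else if (is(result, "SequenceResult")) {
    utils::write.csv(sequenceFrameTable(result), path, row.names = FALSE)
  } else {
    flat <- resultToList(result)
    flat <- flat[vapply(flat, function(x)
      is.atomic(x) && length(x) == 1L, logical(1))]
    utils::write.csv(as.data.frame(flat), path, row.names = FALSE)
  }
  invisible(path)
}
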