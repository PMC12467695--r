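# Frame-by-frame video pipeline: detect, measure, gate, aggregate.  Frames
# are processed independently (no temporal smoothing); a frame counts as a
# diagnostic success when it yields a non-failure alpha measurement and
# passes every quality gate.

#' Default diagnostic-quality gates
#'
#' The gate set operationalizes "diagnostic-quality frame": both landmarks
#' present, each with detector confidence at least \code{minConfidence};
#' measured iliac inclination within \code{maxInclination} degrees of
#' vertical (correct probe positioning); and iliac / roof line-fit RMS
#' residuals below \code{maxIliacRms} / \code{maxRoofRms} px (clean bone
#' surfaces).
#'
#' @param minConfidence minimum per-landmark confidence (default 0.3).
#' @param maxInclination maximum |iliac inclination| in degrees (default 5).
#' @param maxIliacRms maximum iliac-fit RMS residual in px (default 2).
#' @param maxRoofRms maximum roof-fit RMS residual in px (default 3).
#' @return named list of gate values.
#' @export
qualityGates <- function(minConfidence = 0.3, maxInclination = 5,
                         maxIliacRms = 2, maxRoofRms = 3) {
  list(minConfidence = minConfidence, maxInclination = maxInclination,
       maxIliacRms = maxIliacRms, maxRoofRms = maxRoofRms)
}

#' Assess one frame against the diagnostic-quality gates
#'
#' Applies, in order: landmark-presence gates, confidence gates, the
#' measurement-failure gate, the inclination gate, and the residual gates.
#' Reasons accumulate (no short-circuiting), so a report lists everything
#' wrong with a frame.  Every frame yields a report.
#'
#' @param frame the frame (unused by the default gates; kept so custom
#'   gates can inspect pixels).
#' @param detections list of \linkS4class{LandmarkDetection}.
#' @param measurement an \linkS4class{AlphaMeasurement} (possibly a
#'   failure result).
#' @param gates gate values from \code{\link{qualityGates}}.
#' @param frameIndex 1-based frame index for the report.
#' @return a \linkS4class{FrameQualityReport}.
#' @export
assessFrame <- function(frame, detections, measurement,
                        gates = qualityGates(), frameIndex = 1L) {
  labs <- vapply(detections, landmarkLabel, character(1))
  rim <- detections[labs == "acetabular_rim"]
  low <- detections[labs == "ilium_lower_limb"]
  rimConf <- if (length(rim)) confidence(rim[[1]]) else NA_real_
  lowConf <- if (length(low)) confidence(low[[1]]) else NA_real_
  reasons <- character(0)
  if (!length(rim)) reasons <- c(reasons, "rim_not_detected")
  if (!length(low)) reasons <- c(reasons, "lower_limb_not_detected")
  if (length(rim) && rimConf < gates$minConfidence)
    reasons <- c(reasons, "low_confidence")
  if (length(low) && lowConf < gates$minConfidence &&
      !"low_confidence" %in% reasons)
    reasons <- c(reasons, "low_confidence")
  incl <- NA_real_; iliacRms <- NA_real_; roofRms <- NA_real_
  if (isFailure(measurement)) {
    reasons <- c(reasons, "measurement_failed")
  } else {
    incl <- measurement@inclinationDeg
    iliacRms <- measurement@iliacLine@rmsResidual
    roofRms <- measurement@roofLine@rmsResidual
    if (abs(incl) > gates$maxInclination)
      reasons <- c(reasons, "inclination_exceeded")
    if (iliacRms > gates$maxIliacRms)
      reasons <- c(reasons, "iliac_residual_exceeded")
    if (roofRms > gates$maxRoofRms)
      reasons <- c(reasons, "roof_residual_exceeded")
  }
  new("FrameQualityReport", frameIndex = as.integer(frameIndex),
      rimDetected = length(rim) > 0L, lowerLimbDetected = length(low) > 0L,
      rimConfidence = rimConf, lowerLimbConfidence = lowConf,
      inclinationDeg = incl, iliacRms = iliacRms, roofRms = roofRms,
      isDiagnostic = length(reasons) == 0L, rejectReasons = reasons)
}

#' Run the dynamic pipeline over a frame sequence
#'
#' Processes every frame independently: landmark detection, alpha
#' measurement, quality gating.  The per-sequence aggregate (mean and SD of
#' alpha) is computed over diagnostic frames only; a sequence with no
#' diagnostic frame yields an explicit empty aggregate (NA mean/SD, zero
#' count), never an error.
#'
#' @param frames list of \linkS4class{UltrasoundFrame} (or matrices).
#' @param gates gate values from \code{\link{qualityGates}}.
#' @param params measurement parameter overrides (see
#'   \code{\link{measureAlpha}}); entries under \code{params$detect} go to
#'   the detector.
#' @param detector a function frame -> list of
#'   \linkS4class{LandmarkDetection}; defaults to
#'   \code{\link{detectLandmarks}}.  A learned detector satisfying the same
#'   contract can be plugged in here.
#' @param mode "dynamic" (default) or "static".
#' @return a \linkS4class{SequenceResult}.
#' @export
runSequence <- function(frames, gates = qualityGates(), params = list(),
                        detector = NULL, mode = "dynamic") {
  if (!length(frames)) stop("runSequence: need at least one frame")
  detectParams <- if (!is.null(params$detect)) params$detect else list()
  params$detect <- NULL
  if (is.null(detector))
    detector <- function(fr) detectLandmarks(fr, detectParams)
  n <- length(frames)
  measurements <- vector("list", n)
  reports <- vector("list", n)
  for (k in seq_len(n)) {
    dets <- suppressWarnings(detector(frames[[k]]))
    meas <- measureAlpha(frames[[k]], dets, mode = mode, params = params,
                         frameIndex = k)
    measurements[[k]] <- meas
    reports[[k]] <- assessFrame(frames[[k]], dets, meas, gates,
                                frameIndex = k)
  }
  diag <- which(vapply(reports, isDiagnostic, logical(1)))
  alphas <- vapply(measurements[diag], alphaDeg, numeric(1))
  new("SequenceResult", measurements = measurements, reports = reports,
      diagnosticFrames = as.integer(diag),
      alphaMean = if (length(alphas)) mean(alphas) else NA_real_,
      alphaSd = if (length(alphas) > 1L) stats::sd(alphas) else
        if (length(alphas) == 1L) 0 else NA_real_,
      nDiagnostic = length(diag))
}
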