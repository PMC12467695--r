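# Accessor generics.  Slot access from user code should go through these.

#' @rdname UltrasoundFrame-class
#' @param object,x an object.
#' @export
setGeneric("frameData", function(object) standardGeneric("frameData"))
#' @rdname UltrasoundFrame-class
#' @export
setGeneric("pixelSpacing", function(object) standardGeneric("pixelSpacing"))

#' @rdname PhantomScene-class
#' @param object an object.
#' @export
setGeneric("trueAlpha", function(object) standardGeneric("trueAlpha"))
#' @rdname PhantomScene-class
#' @export
setGeneric("trueInclination",
  function(object) standardGeneric("trueInclination"))
#' @rdname PhantomScene-class
#' @export
setGeneric("rimPoint", function(object) standardGeneric("rimPoint"))
#' @rdname PhantomScene-class
#' @export
setGeneric("lowerLimbPoint",
  function(object) standardGeneric("lowerLimbPoint"))

#' @rdname GroundTruth-class
#' @param object an object.
#' @export
setGeneric("isDiagnostic", function(object) standardGeneric("isDiagnostic"))

#' @rdname LineModel-class
#' @param object an object.
#' @export
setGeneric("lineTheta", function(object) standardGeneric("lineTheta"))
#' @rdname LineModel-class
#' @export
setGeneric("lineOffset", function(object) standardGeneric("lineOffset"))
#' @rdname LineModel-class
#' @export
setGeneric("rmsResidual", function(object) standardGeneric("rmsResidual"))

#' @rdname LandmarkDetection-class
#' @param object an object.
#' @export
setGeneric("landmarkLabel",
  function(object) standardGeneric("landmarkLabel"))
#' @rdname LandmarkDetection-class
#' @export
setGeneric("boundingBox", function(object) standardGeneric("boundingBox"))
#' @rdname LandmarkDetection-class
#' @export
setGeneric("confidence", function(object) standardGeneric("confidence"))

#' @rdname AlphaMeasurement-class
#' @param object an object.
#' @export
setGeneric("alphaDeg", function(object) standardGeneric("alphaDeg"))
#' @rdname AlphaMeasurement-class
#' @export
setGeneric("inclinationDeg",
  function(object) standardGeneric("inclinationDeg"))
#' @rdname AlphaMeasurement-class
#' @export
setGeneric("isFailure", function(object) standardGeneric("isFailure"))

#' @rdname SequenceResult-class
#' @param object an object.
#' @export
setGeneric("nDiagnostic", function(object) standardGeneric("nDiagnostic"))
#' @rdname SequenceResult-class
#' @export
setGeneric("alphaMean", function(object) standardGeneric("alphaMean"))

setMethod("frameData", "UltrasoundFrame", function(object) object@data)
setMethod("pixelSpacing", "UltrasoundFrame",
  function(object) object@pixelSpacing)
setMethod("trueAlpha", "PhantomScene", function(object) object@alphaTrue)
setMethod("trueAlpha", "GroundTruth", function(object) object@alphaTrue)
setMethod("trueInclination", "PhantomScene",
  function(object) object@inclinationTrue)
setMethod("trueInclination", "GroundTruth",
  function(object) object@inclinationTrue)
setMethod("rimPoint", "PhantomScene", function(object) object@rimPoint)
setMethod("rimPoint", "GroundTruth", function(object) object@rimPoint)
setMethod("lowerLimbPoint", "PhantomScene",
  function(object) object@lowerLimbPoint)
setMethod("lowerLimbPoint", "GroundTruth",
  function(object) object@lowerLimbPoint)
setMethod("isDiagnostic", "GroundTruth",
  function(object) object@diagnosticQuality)
setMethod("isDiagnostic", "FrameQualityReport",
  function(object) object@isDiagnostic)
setMethod("lineTheta", "LineModel", function(object) object@theta)
setMethod("lineOffset", "LineModel", function(object) object@offset)
setMethod("rmsResidual", "LineModel", function(object) object@rmsResidual)
setMethod("landmarkLabel", "LandmarkDetection",
  function(object) object@label)
setMethod("boundingBox", "LandmarkDetection", function(object) object@box)
setMethod("confidence", "LandmarkDetection",
  function(object) object@confidence)
setMethod("alphaDeg", "AlphaMeasurement", function(object) object@alphaDeg)
setMethod("inclinationDeg", "AlphaMeasurement",
  function(object) object@inclinationDeg)
setMethod("isFailure", "AlphaMeasurement",
  function(object) object@status != "ok")
setMethod("nDiagnostic", "SequenceResult",
  function(object) object@nDiagnostic)
setMethod("alphaMean", "SequenceResult", function(object) object@alphaMean)

setMethod("show", "UltrasoundFrame", function(object) {
  cat(sprintf("UltrasoundFrame %d x %d px, %.3g mm/px, range [%g, %g]\n",
    nrow(object@data), ncol(object@data), object@pixelSpacing,
    min(object@data), max(object@data)))
})

setMethod("show", "PhantomScene", function(object) {
  cat(sprintf(
    "PhantomScene: alpha %.2f deg, inclination %.2f deg, %d x %d canvas\n",
    object@alphaTrue, object@inclinationTrue, object@imageShape[1],
    object@imageShape[2]))
  cat(sprintf("  rim (%.1f, %.1f), lower limb (%.1f, %.1f)\n",
    object@rimPoint[1], object@rimPoint[2], object@lowerLimbPoint[1],
    object@lowerLimbPoint[2]))
})

setMethod("show", "LineModel", function(object) {
  cat(sprintf(
    "LineModel: theta %.3f deg, offset %.2f px, rms %.3f px (n = %d)\n",
    object@theta, object@offset, object@rmsResidual, object@nPoints))
})

setMethod("show", "LandmarkDetection", function(object) {
  cat(sprintf("LandmarkDetection %s: box [%g, %g) x [%g, %g), conf %.2f\n",
    object@label, object@box[1], object@box[3], object@box[2],
    object@box[4], object@confidence))
})

setMethod("show", "AlphaMeasurement", function(object) {
  if (object@status == "ok") {
    cat(sprintf(
      "AlphaMeasurement (%s): alpha %.1f deg, inclination %.1f deg\n",
      object@method, roundHalfAway(object@alphaDeg, 1L),
      roundHalfAway(object@inclinationDeg, 1L)))
  } else {
    cat(sprintf("AlphaMeasurement (%s): FAILED [%s]\n", object@method,
      object@status))
  }
})

setMethod("show", "SequenceResult", function(object) {
  cat(sprintf("SequenceResult: %d/%d diagnostic frames\n",
    object@nDiagnostic, length(object@measurements)))
  if (object@nDiagnostic > 0)
    cat(sprintf("  alpha mean %.1f deg, sd %.2f deg\n",
      roundHalfAway(object@alphaMean, 1L), object@alphaSd))
})

setMethod("show", "AgreementStats", function(object) {
  cat(sprintf(
    "Bland-Altman (n = %d): bias %.1f, SD %.1f, %.0f%% LoA (%.1f, %.1f)\n",
    object@n, roundHalfAway(object@bias, 1L),
    roundHalfAway(object@sdDiff, 1L), 100 * (2 * stats::pnorm(object@z) - 1),
    roundHalfAway(object@loaLower, 1L), roundHalfAway(object@loaUpper, 1L)))
})

setMethod("show", "ICCResult", function(object) {
  cat(sprintf("%s: ICC = %.2f (95%% CI: %.2f-%.2f), %d subjects x %d raters\n",
    object@model, roundHalfAway(object@icc, 2L),
    roundHalfAway(object@ciLower, 2L), roundHalfAway(object@ciUpper, 2L),
    object@nSubjects, object@nRaters))
})

setMethod("show", "AnovaResult", function(object) {
  cat(sprintf(
    "One-way ANOVA: F(%g, %g) = %.2f, p = %.3g, eta2 = %.2f, f = %.2f, power = %.2f\n",
    object@df[1], object@df[2], object@fStat, object@pValue,
    roundHalfAway(object@eta2, 2L), roundHalfAway(object@cohensF, 2L),
    object@power))
})
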