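#' @import methods
#' @importFrom stats median qf pf sd var aggregate
NULL

setClassUnion("numericOrNULL", c("numeric", "NULL"))

#' UltrasoundFrame: a single 2-D grayscale ultrasound-like image
#'
#' Holds one frame as a numeric matrix of 8-bit intensities (0--255),
#' indexed \code{[row, col]} with the origin at the top-left (1-based, the
#' usual R convention), plus the physical pixel spacing in mm per pixel.
#'
#' @slot data numeric matrix of intensities in [0, 255], \code{[row, col]}.
#' @slot pixelSpacing mm per pixel (isotropic).
#' @export
setClass("UltrasoundFrame",
  representation(data = "matrix", pixelSpacing = "numeric"),
  prototype(pixelSpacing = 0.1),
  validity = function(object) {
    d <- object@data
    if (!is.numeric(d) || length(dim(d)) != 2L)
      return("data must be a 2-D numeric matrix")
    if (any(!is.finite(d))) return("data must be finite")
    if (min(d) < 0 || max(d) > 255) return("intensities must lie in [0, 255]")
    if (length(object@pixelSpacing) != 1L || object@pixelSpacing <= 0)
      return("pixelSpacing must be a single positive number")
    TRUE
  })

#' PhantomScene: analytic ground-truth geometry of a Graf standard plane
#'
#' Parametric description of a coronal infant-hip standard plane: the iliac
#' outer margin (a near-vertical bright segment), the bony acetabular roof
#' segment leaving the osseous rim at the true alpha-angle, and the key Graf
#' landmarks.  All geometry is constructed analytically; rasterization only
#' happens at render time, so the stored angle is exact.
#'
#' @slot alphaTrue true Graf alpha-angle in degrees, in (30, 90).
#' @slot inclinationTrue signed tilt of the iliac margin vs the vertical
#'   image axis, degrees, positive clockwise.
#' @slot rimPoint (row, col) of the bony acetabular rim (osseous beak).
#' @slot lowerLimbPoint (row, col) of the lower limb of the ilium, placed at
#'   the medial terminus of the bony roof segment.
#' @slot labrumPoint (row, col) of the labrum tip (metadata only; the labrum
#'   is not used by the alpha measurement).
#' @slot iliacSegment 2x2 matrix, rows = cranial start / caudal end (the rim).
#' @slot roofSegment 2x2 matrix, rows = rim / medial end.
#' @slot imageShape integer (rows, cols) of the rendering canvas.
#' @slot pixelSpacing mm per pixel.
#' @slot ridgeThickness rendered ridge thickness in px.
#' @export
setClass("PhantomScene",
  representation(alphaTrue = "numeric", inclinationTrue = "numeric",
    rimPoint = "numeric", lowerLimbPoint = "numeric", labrumPoint = "numeric",
    iliacSegment = "matrix", roofSegment = "matrix",
    imageShape = "integer", pixelSpacing = "numeric",
    ridgeThickness = "numeric"),
  validity = function(object) {
    if (object@alphaTrue <= 30 || object@alphaTrue > 90)
      return("alphaTrue must lie in (30, 90] degrees")
    if (abs(object@inclinationTrue) >= 30)
      return("inclinationTrue must lie in (-30, 30) degrees")
    segAng <- segmentAngleDeg(object@iliacSegment, object@roofSegment)
    if (abs(segAng - object@alphaTrue) > 1e-9)
      return(sprintf("segment angle %.12f != alphaTrue %.12f", segAng,
                     object@alphaTrue))
    if (sqrt(sum((object@iliacSegment[2, ] - object@rimPoint)^2)) > 1)
      return("rimPoint must lie within 1 px of the iliac segment's lower end")
    TRUE
  })

#' NoiseConfig: acoustic artifact model for the phantom renderer
#'
#' The simplest noise model preserving the one property the measurement
#' pipeline relies on: bone surfaces are intensity ridges.  Multiplicative
#' Rayleigh-like speckle, then a Gaussian point-spread blur, then a
#' column-wise acoustic shadow below the deepest bone surface.
#'
#' @slot speckleScale blend weight of unit-mean Rayleigh multiplicative
#'   speckle, >= 0 (0 disables).
#' @slot blurSigma Gaussian point-spread sigma in px, >= 0 (0 disables).
#' @slot shadowAttenuation fraction in [0, 1] removed below bone surfaces.
#' @slot backgroundLevel background intensity in [0, 255].
#' @slot boneIntensity ridge intensity in [0, 255], > backgroundLevel.
#' @export
setClass("NoiseConfig",
  representation(speckleScale = "numeric", blurSigma = "numeric",
    shadowAttenuation = "numeric", backgroundLevel = "numeric",
    boneIntensity = "numeric"),
  prototype(speckleScale = 0.2, blurSigma = 1.0, shadowAttenuation = 0.3,
    backgroundLevel = 20, boneIntensity = 220),
  validity = function(object) {
    if (object@speckleScale < 0) return("speckleScale must be >= 0")
    if (object@blurSigma < 0) return("blurSigma must be >= 0")
    if (object@shadowAttenuation < 0 || object@shadowAttenuation > 1)
      return("shadowAttenuation must lie in [0, 1]")
    if (object@backgroundLevel < 0 || object@backgroundLevel > 255)
      return("backgroundLevel must lie in [0, 255]")
    if (object@boneIntensity <= object@backgroundLevel ||
        object@boneIntensity > 255)
      return("boneIntensity must lie in (backgroundLevel, 255]")
    TRUE
  })

#' DriftModel: probe drift for synthetic video sequences
#'
#' Emulates slow probe drift during continuous scanning: a per-frame
#' rotation about the rim plus a per-frame translation, with a designated
#' set of off-plane frames whose landmark contrast is degraded.  Frame 1 is
#' undrifted; the ground truth of frame k is the scene transformed by k - 1
#' accumulated drift steps.
#'
#' @slot rotationPerFrame degrees per frame (positive clockwise).
#' @slot translationPerFrame (row, col) px per frame.
#' @slot offplaneFrames integer frame indices (1-based) rendered off-plane.
#' @slot offplaneContrast factor in (0, 1) applied to ridge contrast on
#'   off-plane frames (default 0.3).
#' @export
setClass("DriftModel",
  representation(rotationPerFrame = "numeric",
    translationPerFrame = "numeric", offplaneFrames = "integer",
    offplaneContrast = "numeric"),
  prototype(rotationPerFrame = 0, translationPerFrame = c(0, 0),
    offplaneFrames = integer(0), offplaneContrast = 0.3),
  validity = function(object) {
    if (length(object@translationPerFrame) != 2L)
      return("translationPerFrame must be (row, col)")
    if (object@offplaneContrast <= 0 || object@offplaneContrast >= 1)
      return("offplaneContrast must lie in (0, 1)")
    TRUE
  })

#' GroundTruth: per-frame reference geometry for a rendered phantom frame
#'
#' @slot alphaTrue degrees.
#' @slot inclinationTrue degrees.
#' @slot rimPoint,lowerLimbPoint (row, col).
#' @slot rimBox,lowerLimbBox (rowMin, colMin, rowMax, colMax), half-open on
#'   the max edges.
#' @slot diagnosticQuality FALSE exactly for off-plane frames.
#' @slot frameIndex 1-based index within its sequence.
#' @export
setClass("GroundTruth",
  representation(alphaTrue = "numeric", inclinationTrue = "numeric",
    rimPoint = "numeric", lowerLimbPoint = "numeric",
    rimBox = "numeric", lowerLimbBox = "numeric",
    diagnosticQuality = "logical", frameIndex = "integer"))

#' LandmarkDetection: a labelled landmark bounding box
#'
#' @slot label "acetabular_rim" or "ilium_lower_limb".
#' @slot box (rowMin, colMin, rowMax, colMax) px, half-open on max edges.
#' @slot confidence normalized local ridge contrast in [0, 1].
#' @export
setClass("LandmarkDetection",
  representation(label = "character", box = "numeric",
    confidence = "numeric"),
  validity = function(object) {
    if (!object@label %in% c("acetabular_rim", "ilium_lower_limb"))
      return("unknown label")
    b <- object@box
    if (length(b) != 4L || b[1] >= b[3] || b[2] >= b[4])
      return("box must be (rowMin, colMin, rowMax, colMax) with min < max")
    if (object@confidence < 0 || object@confidence > 1)
      return("confidence must lie in [0, 1]")
    TRUE
  })

#' LineModel: a 2-D line in direction-angle / offset form
#'
#' The line direction is \code{d(theta) = (cos theta, sin theta)} in
#' (row, col) coordinates with theta in [0, 180) degrees measured from the
#' image column (vertical) axis, positive clockwise; theta = 0 is a vertical
#' line, theta = 90 a horizontal one.  The unit normal is
#' \code{n(theta) = (-sin theta, cos theta)} and the line is the locus
#' \code{n . p = offset}, so \code{offset} is the signed perpendicular
#' distance from the image origin in px.
#'
#' @slot theta degrees in [0, 180).
#' @slot offset signed perpendicular distance from the origin, px.
#' @slot rmsResidual root-mean-square perpendicular residual of the fit, px.
#' @slot nPoints number of supporting points.
#' @export
setClass("LineModel",
  representation(theta = "numeric", offset = "numeric",
    rmsResidual = "numeric", nPoints = "integer"),
  validity = function(object) {
    if (object@theta < 0 || object@theta >= 180)
      return("theta must lie in [0, 180)")
    if (object@rmsResidual < 0) return("rmsResidual must be >= 0")
    if (object@nPoints < 2L) return("a line needs >= 2 supporting points")
    TRUE
  })

setClassUnion("LineModelOrNULL", c("LineModel", "NULL"))

#' PointSet: candidate bone-surface points with their intensities
#'
#' @slot coords n x 2 matrix of (row, col) pixel coordinates.
#' @slot intensities intensity of the source frame at each coordinate.
#' @export
setClass("PointSet",
  representation(coords = "matrix", intensities = "numeric"),
  validity = function(object) {
    if (ncol(object@coords) != 2L && nrow(object@coords) > 0L)
      return("coords must be an n x 2 matrix")
    if (nrow(object@coords) != length(object@intensities))
      return("one intensity per coordinate required")
    TRUE
  })

#' AlphaMeasurement: one alpha-angle measurement with audit trail
#'
#' \code{status == "ok"} marks a successful measurement; any other value is
#' a reason code for a structured failure (e.g. "rim_not_detected",
#' "roof_fit_failed") and the numeric slots are NA.
#'
#' @slot status "ok" or a failure reason code.
#' @slot alphaDeg measured Graf alpha-angle, degrees.
#' @slot inclinationDeg signed iliac inclination vs the vertical axis.
#' @slot baseline LineModel through the rim, parallel to the iliac margin.
#' @slot roofLine LineModel of the bony acetabular roof.
#' @slot iliacLine LineModel fitted to the iliac outer margin.
#' @slot method "static" (Hough-seeded) or "dynamic" (screened-maxima TLS).
#' @slot frameIndex 1-based frame index, or NA.
#' @export
setClass("AlphaMeasurement",
  representation(status = "character", alphaDeg = "numeric",
    inclinationDeg = "numeric", baseline = "LineModelOrNULL",
    roofLine = "LineModelOrNULL", iliacLine = "LineModelOrNULL",
    method = "character", frameIndex = "integer"),
  prototype(frameIndex = NA_integer_),
  validity = function(object) {
    if (!object@method %in% c("static", "dynamic"))
      return("method must be 'static' or 'dynamic'")
    if (object@status == "ok") {
      if (is.null(object@baseline) || is.null(object@roofLine))
        return("an ok measurement must carry baseline and roof lines")
      a <- thetaSeparationDeg(object@baseline@theta, object@roofLine@theta)
      if (abs(a - object@alphaDeg) > 1e-6)
        return("alphaDeg inconsistent with baseline/roof thetas")
    }
    TRUE
  })

#' FrameQualityReport: diagnostic-quality gating result for one frame
#'
#' @slot frameIndex 1-based frame index.
#' @slot rimDetected,lowerLimbDetected landmark presence flags.
#' @slot rimConfidence,lowerLimbConfidence detector confidences (NA if absent).
#' @slot inclinationDeg measured iliac inclination (NA on failure).
#' @slot iliacRms,roofRms line-fit RMS residuals in px (NA on failure).
#' @slot isDiagnostic TRUE iff rejectReasons is empty.
#' @slot rejectReasons character vector of gate-failure codes.
#' @export
setClass("FrameQualityReport",
  representation(frameIndex = "integer", rimDetected = "logical",
    lowerLimbDetected = "logical", rimConfidence = "numeric",
    lowerLimbConfidence = "numeric", inclinationDeg = "numeric",
    iliacRms = "numeric", roofRms = "numeric", isDiagnostic = "logical",
    rejectReasons = "character"),
  validity = function(object) {
    if (object@isDiagnostic != (length(object@rejectReasons) == 0L))
      return("isDiagnostic must be TRUE exactly when rejectReasons is empty")
    TRUE
  })

#' SequenceResult: per-frame measurements and diagnostic-frame aggregate
#'
#' @slot measurements list of AlphaMeasurement (one per frame).
#' @slot reports list of FrameQualityReport (one per frame).
#' @slot diagnosticFrames indices of frames passing all gates.
#' @slot alphaMean,alphaSd mean/SD of alpha over diagnostic frames (NA when
#'   no frame is diagnostic).
#' @slot nDiagnostic number of diagnostic frames.
#' @export
setClass("SequenceResult",
  representation(measurements = "list", reports = "list",
    diagnosticFrames = "integer", alphaMean = "numeric", alphaSd = "numeric",
    nDiagnostic = "integer"),
  validity = function(object) {
    if (object@nDiagnostic != length(object@diagnosticFrames))
      return("nDiagnostic must equal length(diagnosticFrames)")
    TRUE
  })

#' AgreementStats: Bland-Altman agreement against a reference
#'
#' @slot bias mean difference (measurement - reference), degrees.
#' @slot sdDiff sample SD of the differences (n - 1 denominator).
#' @slot loaLower,loaUpper bias -/+ z * sdDiff.
#' @slot n number of paired differences.
#' @slot z limits-of-agreement multiplier (1.96 for 95% limits).
#' @export
setClass("AgreementStats",
  representation(bias = "numeric", sdDiff = "numeric", loaLower = "numeric",
    loaUpper = "numeric", n = "integer", z = "numeric"),
  validity = function(object) {
    if (abs(object@loaLower - (object@bias - object@z * object@sdDiff)) > 1e-9)
      return("loaLower must equal bias - z * sdDiff")
    if (abs(object@loaUpper - (object@bias + object@z * object@sdDiff)) > 1e-9)
      return("loaUpper must equal bias + z * sdDiff")
    TRUE
  })

#' ICCResult: intraclass correlation with its 95% confidence interval
#'
#' @slot icc point estimate.
#' @slot ciLower,ciUpper 95% CI bounds (F-based).
#' @slot model model label, e.g. "ICC(2,1) two-way random, absolute
#'   agreement, single measurement".
#' @slot nSubjects,nRaters design dimensions.
#' @slot meanSquares named numeric (MSR, MSC, MSE) from the two-way ANOVA.
#' @export
setClass("ICCResult",
  representation(icc = "numeric", ciLower = "numeric", ciUpper = "numeric",
    model = "character", nSubjects = "integer", nRaters = "integer",
    meanSquares = "numeric"),
  validity = function(object) {
    if (object@ciLower > object@icc + 1e-9 ||
        object@ciUpper < object@icc - 1e-9)
      return("CI must bracket the point estimate")
    TRUE
  })

#' AnovaResult: one-way ANOVA with effect sizes and post-hoc power
#'
#' @slot fStat F statistic.
#' @slot pValue p-value.
#' @slot eta2 SS_between / SS_total.
#' @slot cohensF sqrt(eta2 / (1 - eta2)).
#' @slot power post-hoc power at the observed effect size (alpha = 0.05),
#'   from the noncentral-F distribution.
#' @slot groupNs per-group sample sizes.
#' @slot df (df_between, df_within).
#' @slot sumSquares named numeric (SSB, SSW, SST).
#' @export
setClass("AnovaResult",
  representation(fStat = "numeric", pValue = "numeric", eta2 = "numeric",
    cohensF = "numeric", power = "numeric", groupNs = "integer",
    df = "numeric", sumSquares = "numeric"),
  validity = function(object) {
    ss <- object@sumSquares
    if (all(c("SSB", "SST") %in% names(ss)) && ss[["SST"]] > 0 &&
        abs(object@eta2 - ss[["SSB"]] / ss[["SST"]]) > 1e-9)
      return("eta2 must equal SSB / SST")
    TRUE
  })
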