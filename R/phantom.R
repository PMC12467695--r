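# Synthetic digital phantom of the Graf standard plane.  The physical
# reference is a standardized infant-hip phantom scanned with the iliac
# outer margin aligned vertically; its acoustic and geometric parameters
# (beyond the reference alpha-angle) are not published, so the scene layout
# below is an explicit, fixed artifact choice recorded in the scene object.

#' Convenience constructor for \linkS4class{NoiseConfig}
#'
#' @param speckleScale,blurSigma,shadowAttenuation,backgroundLevel,boneIntensity
#'   see \linkS4class{NoiseConfig}.
#' @return a \linkS4class{NoiseConfig}.
#' @export
noiseConfig <- function(speckleScale = 0.2, blurSigma = 1.0,
                        shadowAttenuation = 0.3, backgroundLevel = 20,
                        boneIntensity = 220) {
  new("NoiseConfig", speckleScale = speckleScale, blurSigma = blurSigma,
      shadowAttenuation = shadowAttenuation,
      backgroundLevel = backgroundLevel, boneIntensity = boneIntensity)
}

#' Convenience constructor for \linkS4class{DriftModel}
#'
#' @param rotationPerFrame,translationPerFrame,offplaneFrames,offplaneContrast
#'   see \linkS4class{DriftModel}.
#' @return a \linkS4class{DriftModel}.
#' @export
driftModel <- function(rotationPerFrame = 0, translationPerFrame = c(0, 0),
                       offplaneFrames = integer(0), offplaneContrast = 0.3) {
  new("DriftModel", rotationPerFrame = rotationPerFrame,
      translationPerFrame = as.numeric(translationPerFrame),
      offplaneFrames = as.integer(offplaneFrames),
      offplaneContrast = offplaneContrast)
}

#' Build an analytic Graf standard-plane phantom scene
#'
#' The iliac outer margin is a segment ending caudally at the bony
#' acetabular rim (osseous beak); the bony roof segment leaves the rim at
#' exactly \code{alphaDeg} to the iliac direction, descending medially.
#' The lower limb of the ilium sits at the roof's medial terminus (Graf's
#' roof line runs from the lower limb through the rim).  All coordinates
#' are computed analytically, so the stored angle is exact; rasterization
#' happens only in \code{\link{renderFrame}}.
#'
#' @param alphaDeg true alpha-angle, degrees, in (30, 90] (90 gives the
#'   perpendicular roof, a useful degenerate test case).
#' @param inclinationDeg signed iliac tilt vs the vertical axis, degrees,
#'   |inclination| < 30, positive clockwise.
#' @param imageShape canvas (rows, cols); default 256 x 256.
#' @param geometry optional overrides: \code{rim} (row, col),
#'   \code{iliacLength}, \code{roofLength} (px), \code{ridgeThickness}
#'   (px), \code{pixelSpacing} (mm/px).
#' @return a \linkS4class{PhantomScene}.
#' @examples
#' sc <- makeScene(70, 0)
#' trueAlpha(sc)
#' @export
makeScene <- function(alphaDeg, inclinationDeg = 0,
                      imageShape = c(256L, 256L), geometry = list()) {
  if (!is.numeric(alphaDeg) || length(alphaDeg) != 1L ||
      alphaDeg <= 30 || alphaDeg > 90)
    stop("alphaDeg must be a single number in (30, 90]")
  if (!is.numeric(inclinationDeg) || length(inclinationDeg) != 1L ||
      abs(inclinationDeg) >= 30)
    stop("inclinationDeg must satisfy |inclination| < 30")
  g <- utils::modifyList(list(rim = c(150, 110), iliacLength = 110,
    roofLength = 70, ridgeThickness = 2, pixelSpacing = 0.1), geometry)
  rim <- as.numeric(g$rim)
  dIliac <- lineDir(inclinationDeg)            # caudal direction
  dRoof <- lineDir(inclinationDeg - alphaDeg)  # medial, down-left for alpha<90
  iliacSeg <- unname(rbind(rim - g$iliacLength * dIliac, rim))
  roofSeg <- unname(rbind(rim, rim + g$roofLength * dRoof))
  labrum <- rim + 22 * lineDir(inclinationDeg - alphaDeg / 2)
  new("PhantomScene", alphaTrue = alphaDeg, inclinationTrue = inclinationDeg,
      rimPoint = rim, lowerLimbPoint = roofSeg[2, ], labrumPoint = labrum,
      iliacSegment = iliacSeg, roofSegment = roofSeg,
      imageShape = as.integer(imageShape), pixelSpacing = g$pixelSpacing,
      ridgeThickness = g$ridgeThickness)
}

# rigid transform of a scene: rotate by deltaDeg (clockwise positive, about
# `center`) then translate by (row, col).  Angles are preserved, so
# alphaTrue is unchanged and inclination gains deltaDeg.
transformScene <- function(scene, deltaDeg = 0, translation = c(0, 0),
                           center = scene@rimPoint) {
  rot <- function(p) {
    cd <- cos(deltaDeg * DEG); sdv <- sin(deltaDeg * DEG)
    p <- rbind(p)
    sw <- sweep(p, 2, center)
    out <- cbind(cd * sw[, 1] - sdv * sw[, 2], sdv * sw[, 1] + cd * sw[, 2])
    sweep(sweep(out, 2, center, "+"), 2, translation, "+")
  }
  sc <- scene
  sc@rimPoint <- drop(rot(scene@rimPoint))
  sc@lowerLimbPoint <- drop(rot(scene@lowerLimbPoint))
  sc@labrumPoint <- drop(rot(scene@labrumPoint))
  sc@iliacSegment <- rot(scene@iliacSegment)
  sc@roofSegment <- rot(scene@roofSegment)
  sc@inclinationTrue <- scene@inclinationTrue + deltaDeg
  validObject(sc)
  sc
}

# rasterize a segment as the set of pixels whose center lies within
# thickness/2 px of it (perpendicular distance, projection clamped to the
# segment); returns integer (row, col) pixels clipped to the canvas
rasterizeSegment <- function(p1, p2, shape, thickness = 2) {
  v <- p2 - p1
  len <- sqrt(sum(v^2))
  if (len == 0) return(matrix(numeric(0), 0, 2))
  d <- v / len
  nrm <- c(-d[2], d[1])
  h <- thickness / 2
  rr <- max(1, floor(min(p1[1], p2[1]) - h)):min(shape[1],
            ceiling(max(p1[1], p2[1]) + h))
  cc <- max(1, floor(min(p1[2], p2[2]) - h)):min(shape[2],
            ceiling(max(p1[2], p2[2]) + h))
  pts <- cbind(rep(rr, times = length(cc)), rep(cc, each = length(rr)))
  rel <- sweep(pts, 2, p1)
  tproj <- rel %*% d
  dist <- abs(rel %*% nrm)
  keep <- tproj >= 0 & tproj <= len & dist <= h
  pts[keep, , drop = FALSE]
}

# logical canvas mask of all bone ridge pixels of a scene
sceneRidgeMask <- function(scene) {
  shape <- scene@imageShape
  m <- matrix(FALSE, shape[1], shape[2])
  for (seg in list(scene@iliacSegment, scene@roofSegment)) {
    px <- rasterizeSegment(seg[1, ], seg[2, ], shape, scene@ridgeThickness)
    m[px] <- TRUE
  }
  m
}

# landmark box around a keypoint: (rowMin, colMin, rowMax, colMax),
# half-open on the max edges, clipped to the canvas
keypointBox <- function(pt, shape, size = 24) {
  h <- size / 2
  c(max(1, pt[1] - h), max(1, pt[2] - h),
    min(shape[1] + 1, pt[1] + h), min(shape[2] + 1, pt[2] + h))
}

makeGroundTruth <- function(scene, diagnostic = TRUE, frameIndex = 1L,
                            boxSize = 24) {
  shape <- scene@imageShape
  new("GroundTruth", alphaTrue = scene@alphaTrue,
      inclinationTrue = scene@inclinationTrue, rimPoint = scene@rimPoint,
      lowerLimbPoint = scene@lowerLimbPoint,
      rimBox = keypointBox(scene@rimPoint, shape, boxSize),
      lowerLimbBox = keypointBox(scene@lowerLimbPoint, shape, boxSize),
      diagnosticQuality = diagnostic, frameIndex = as.integer(frameIndex))
}

#' Render one synthetic ultrasound frame from a phantom scene
#'
#' Paints the bone ridges onto a uniform background, then applies (in
#' order) multiplicative unit-mean Rayleigh-like speckle, a Gaussian
#' point-spread blur, and a column-wise acoustic shadow below the deepest
#' bone surface of each column, and finally quantizes to 8 bits.  With
#' \code{speckleScale = 0} and \code{blurSigma = 0} the ridge pixels are
#' exactly the rasterized scene segments.  Identical (scene, noise, seed)
#' inputs give bit-identical frames.
#'
#' @param scene a \linkS4class{PhantomScene}.
#' @param noise a \linkS4class{NoiseConfig}.
#' @param seed integer RNG seed (required: rendering must be reproducible).
#' @param contrastFactor factor in (0, 1] applied to the ridge-background
#'   contrast; used by \code{\link{renderSequence}} for off-plane frames.
#' @param frameIndex 1-based index recorded in the ground truth.
#' @param diagnostic diagnostic-quality flag recorded in the ground truth.
#' @return \code{list(frame = UltrasoundFrame, truth = GroundTruth)}.
#' @examples
#' sc <- makeScene(70, 0)
#' fr <- renderFrame(sc, noiseConfig(), seed = 1)
#' fr$frame
#' @export
renderFrame <- function(scene, noise = noiseConfig(), seed,
                        contrastFactor = 1, frameIndex = 1L,
                        diagnostic = TRUE) {
  stopifnot(is(scene, "PhantomScene"), is(noise, "NoiseConfig"))
  if (missing(seed)) stop("renderFrame: an explicit seed is required")
  validObject(noise)
  shape <- scene@imageShape
  bg <- noise@backgroundLevel
  bone <- bg + contrastFactor * (noise@boneIntensity - bg)
  img <- matrix(bg, shape[1], shape[2])
  mask <- sceneRidgeMask(scene)
  img[mask] <- bone
  set.seed(as.integer(seed))
  if (noise@speckleScale > 0) {
    ray <- sqrt(-2 * log(stats::runif(length(img)))) * sqrt(2 / pi)
    m <- (1 - noise@speckleScale) + noise@speckleScale * ray
    img <- img * matrix(m, shape[1], shape[2])
  }
  if (noise@blurSigma > 0)
    img <- EBImage::gblur(img, sigma = noise@blurSigma,
                          boundary = "replicate")
  if (noise@shadowAttenuation > 0) {
    lastBone <- apply(mask, 2, function(colMask)
      if (any(colMask)) max(which(colMask)) else NA_integer_)
    for (j in which(!is.na(lastBone))) {
      r0 <- lastBone[j] + 3
      if (r0 <= shape[1])
        img[r0:shape[1], j] <- img[r0:shape[1], j] *
          (1 - noise@shadowAttenuation)
    }
  }
  img <- round(pmin(pmax(img, 0), 255))
  frame <- new("UltrasoundFrame", data = img,
               pixelSpacing = scene@pixelSpacing)
  list(frame = frame,
       truth = makeGroundTruth(scene, diagnostic = diagnostic,
                               frameIndex = frameIndex))
}

#' Render a drifting synthetic video sequence
#'
#' Frame 1 is the undrifted scene; frame k is the scene rotated by
#' \code{(k - 1) * rotationPerFrame} about the original rim point and
#' translated by \code{(k - 1) * translationPerFrame}.  Frames listed in
#' \code{drift@offplaneFrames} are rendered with ridge contrast scaled by
#' \code{drift@offplaneContrast} and flagged \code{diagnosticQuality =
#' FALSE} in their ground truth.
#'
#' @param scene a \linkS4class{PhantomScene}.
#' @param nFrames number of frames (>= 1).
#' @param drift a \linkS4class{DriftModel}.
#' @param noise a \linkS4class{NoiseConfig}.
#' @param seed integer; frame k is rendered with seed \code{seed + k - 1}.
#' @return \code{list(frames = list of UltrasoundFrame, truths = list of
#'   GroundTruth)}.
#' @export
renderSequence <- function(scene, nFrames, drift = driftModel(),
                           noise = noiseConfig(), seed) {
  stopifnot(is(drift, "DriftModel"))
  if (missing(seed)) stop("renderSequence: an explicit seed is required")
  nFrames <- as.integer(nFrames)
  if (nFrames < 1L) stop("nFrames must be >= 1")
  if (length(drift@offplaneFrames) &&
      (min(drift@offplaneFrames) < 1L || max(drift@offplaneFrames) > nFrames))
    stop("offplaneFrames indices must lie in [1, nFrames]")
  center <- scene@rimPoint
  frames <- vector("list", nFrames)
  truths <- vector("list", nFrames)
  for (k in seq_len(nFrames)) {
    sck <- transformScene(scene, deltaDeg = (k - 1) * drift@rotationPerFrame,
                          translation = (k - 1) * drift@translationPerFrame,
                          center = center)
    off <- k %in% drift@offplaneFrames
    rf <- renderFrame(sck, noise, seed = seed + k - 1L,
                      contrastFactor = if (off) drift@offplaneContrast else 1,
                      frameIndex = k, diagnostic = !off)
    frames[[k]] <- rf$frame
    truths[[k]] <- rf$truth
  }
  list(frames = frames, truths = truths)
}
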