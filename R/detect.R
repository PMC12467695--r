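# Deterministic classical reference detector for the two Graf landmarks.
# It satisfies the same contract a learned bounding-box detector would
# (frame -> at most one labelled box per landmark, rim first, with a
# confidence score), so a trained model can be substituted without touching
# the downstream geometry.

defaultDetectParams <- function(params = list()) {
  utils::modifyList(list(minSeparation = 3, screenK = 2, minSupport = 5,
    boxSize = 24, confFloor = 0.1, inlierDist = 2.5, iliacExclude = 3,
    thetaBin = 1, rhoBin = 1), params)
}

detectionConfidence <- function(chainInts, frameMat) {
  bg <- stats::median(frameMat)
  if (bg >= 255) return(0)
  conf <- (stats::median(chainInts) - bg) / (255 - bg)
  max(0, min(1, conf))
}

#' Detect the Graf landmarks on a frame
#'
#' Locates the bony acetabular rim (osseous beak) and the lower limb of the
#' ilium and returns a labelled bounding box per landmark, rim first.  The
#' reference implementation is classical and fully deterministic: per-row
#' ridge maxima are screened by intensity, the dominant near-vertical chain
#' (the iliac outer margin) is found by a Hough transform, the rim is its
#' caudal terminus (ties broken toward the greater row), and the lower limb
#' is the terminus of the remaining (roof) chain farthest from the iliac
#' line.  Boxes are fixed-size (default 24 x 24 px) and centered on the
#' located keypoint; confidence is the normalized local ridge contrast in
#' [0, 1], and no detection is emitted below the contrast floor.
#'
#' @param frame an \linkS4class{UltrasoundFrame} or numeric matrix, 8-bit
#'   grayscale.
#' @param params named list of overrides: minSeparation, screenK,
#'   minSupport, boxSize, confFloor, inlierDist, iliacExclude, thetaBin,
#'   rhoBin.
#' @return list of 0--2 \linkS4class{LandmarkDetection} objects (rim before
#'   lower limb).  Degenerate input (constant or non-grayscale) yields an
#'   empty list with a warning, never an error.
#' @examples
#' sc <- makeScene(70, 0)
#' fr <- renderFrame(sc, noiseConfig(speckleScale = 0, blurSigma = 0,
#'   shadowAttenuation = 0), seed = 1)
#' detectLandmarks(fr$frame)
#' @export
detectLandmarks <- function(frame, params = list()) {
  p <- defaultDetectParams(params)
  m <- if (is(frame, "UltrasoundFrame")) frame@data else frame
  if (!is.numeric(m) || length(dim(m)) != 2L) {
    warning("detectLandmarks: frame is not 2-D grayscale; nothing detected")
    return(list())
  }
  if (min(m) == max(m)) {
    warning("detectLandmarks: constant frame; nothing detected")
    return(list())
  }
  shape <- dim(m)
  pp <- preprocessFrame(m)
  ps <- extractLocalMaxima(pp, "rows", p$minSeparation)
  sp <- screenPeaks(ps, k = p$screenK, minSupport = p$minSupport,
                    frame = pp)
  cd <- sp@coords
  if (nrow(unique(cd)) < 2L) {
    warning("detectLandmarks: no screened ridge points; nothing detected")
    return(list())
  }
  iliacLine <- houghFit(cd, p$thetaBin, p$rhoBin)
  dIl <- linePointDistance(iliacLine, cd)
  inl <- abs(dIl) <= p$inlierDist
  if (sum(inl) < 2L) return(list())
  ilPts <- cd[inl, , drop = FALSE]
  ilInts <- sp@intensities[inl]
  # caudal terminus of the iliac chain = rim; ties -> greater row
  dirv <- lineDir(iliacLine@theta)
  if (dirv[1] < 0) dirv <- -dirv        # point caudally (increasing row)
  proj <- ilPts %*% dirv
  tmax <- max(proj)
  candIdx <- which(proj >= tmax - 0.5)
  rimPt <- ilPts[candIdx[which.max(ilPts[candIdx, 1])], ]
  near <- sqrt(rowSums(sweep(ilPts, 2, rimPt)^2)) <= 20
  rimConf <- detectionConfidence(ilInts[near], m)
  out <- list()
  if (rimConf >= p$confFloor) {
    out[[length(out) + 1L]] <- new("LandmarkDetection",
      label = "acetabular_rim",
      box = keypointBox(rimPt, shape, p$boxSize), confidence = rimConf)
  }
  # lower limb: terminus of the non-iliac (roof) chain farthest from the
  # iliac line
  offIdx <- which(abs(dIl) > p$iliacExclude)
  if (length(offIdx) >= 2L) {
    roofPts <- cd[offIdx, , drop = FALSE]
    roofInts <- sp@intensities[offIdx]
    if (nrow(unique(roofPts)) >= 2L) {
      roofLine <- houghFit(roofPts, p$thetaBin, p$rhoBin)
      rinl <- abs(linePointDistance(roofLine, roofPts)) <= p$inlierDist
      if (sum(rinl) >= 2L) {
        rp <- roofPts[rinl, , drop = FALSE]
        ri <- roofInts[rinl]
        far <- abs(linePointDistance(iliacLine, rp))
        lowPt <- rp[which.max(far), ]
        nearL <- sqrt(rowSums(sweep(rp, 2, lowPt)^2)) <= 20
        lowConf <- detectionConfidence(ri[nearL], m)
        if (lowConf >= p$confFloor) {
          out[[length(out) + 1L]] <- new("LandmarkDetection",
            label = "ilium_lower_limb",
            box = keypointBox(lowPt, shape, p$boxSize),
            confidence = lowConf)
        }
      }
    }
  }
  out
}
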