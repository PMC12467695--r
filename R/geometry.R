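# Core alpha-angle measurement: bone-surface ridge extraction, peak
# screening, iliac baseline and bony-roof line construction, and the Graf
# angle computation.  Two paths are provided: "static" seeds the line fits
# with a Hough transform; "dynamic" fits screened local maxima directly by
# total least squares (the faster per-frame path for video).

asFrameMatrix <- function(frame) {
  if (is(frame, "UltrasoundFrame")) frame@data else frame
}

#' Preprocess a frame (noise suppression)
#'
#' A 3 x 3 median filter: suppresses impulsive (salt) noise and mild
#' speckle while preserving the bone ridges the downstream fits rely on.
#' Shape and intensity range are preserved and the operation is idempotent
#' up to a small tolerance.
#'
#' @param frame an \linkS4class{UltrasoundFrame} or numeric matrix.
#' @return the same type as the input.
#' @export
preprocessFrame <- function(frame) {
  m <- asFrameMatrix(frame)
  out <- EBImage::medianFilter(m / 255, size = 1L) * 255
  out <- pmin(pmax(out, 0), 255)
  if (is(frame, "UltrasoundFrame")) {
    frame@data <- out
    frame
  } else out
}

#' Extract per-scanline strict local intensity maxima
#'
#' Scans each row (scanAxis = "rows", the default: the near-vertical iliac
#' margin crosses every row exactly once) or each column, and returns all
#' strict local maxima, at least \code{minSeparation} px apart within a
#' scanline.  A flat plateau flanked by lower values counts once, at its
#' center; plateau-interior pixels and scanline endpoints are never
#' returned.  A constant frame yields an empty set.
#'
#' @param frame an \linkS4class{UltrasoundFrame} or numeric matrix
#'   (preprocessed).
#' @param scanAxis "rows" or "cols".
#' @param minSeparation minimum spacing of maxima within one scanline, px.
#' @return a \linkS4class{PointSet}.
#' @export
extractLocalMaxima <- function(frame, scanAxis = c("rows", "cols"),
                               minSeparation = 3) {
  scanAxis <- match.arg(scanAxis)
  m <- asFrameMatrix(frame)
  if (scanAxis == "cols") m <- t(m)
  rows <- integer(0); cols <- integer(0); ints <- numeric(0)
  for (r in seq_len(nrow(m))) {
    v <- m[r, ]
    rl <- rle(v)
    k <- length(rl$values)
    if (k < 3L) next
    ends <- cumsum(rl$lengths)
    starts <- ends - rl$lengths + 1L
    isMax <- c(FALSE, rl$values[2:(k - 1)] > rl$values[1:(k - 2)] &
                      rl$values[2:(k - 1)] > rl$values[3:k], FALSE)
    if (!any(isMax)) next
    pos <- floor((starts[isMax] + ends[isMax]) / 2)
    val <- rl$values[isMax]
    if (length(pos) > 1L) {
      ord <- order(val, decreasing = TRUE)
      keep <- logical(length(pos))
      kept <- numeric(0)
      for (i in ord) {
        if (!length(kept) || all(abs(kept - pos[i]) >= minSeparation)) {
          keep[i] <- TRUE
          kept <- c(kept, pos[i])
        }
      }
      pos <- pos[keep]; val <- val[keep]
    }
    rows <- c(rows, rep.int(r, length(pos)))
    cols <- c(cols, pos)
    ints <- c(ints, val)
  }
  coords <- cbind(row = rows, col = cols)
  if (scanAxis == "cols") coords <- coords[, 2:1, drop = FALSE]
  colnames(coords) <- c("row", "col")
  new("PointSet", coords = coords, intensities = ints)
}

# single-linkage spatial components with the given linking distance; 7 px
# keeps an oblique bony-roof chain connected even where plateau-center
# quantization makes successive per-row peaks jump several columns
peakComponents <- function(coords, linkDist = 7) {
  n <- nrow(coords)
  if (n <= 1L) return(rep.int(1L, n))
  hc <- stats::hclust(stats::dist(coords), method = "single")
  stats::cutree(hc, h = linkDist)
}

#' Screen candidate peaks by intensity (and optional chain support)
#'
#' Intensity-based filtering of minor peaks: retains points whose intensity
#' is at least \code{threshold}; when no explicit threshold is given it is
#' set to \code{mean + k * sd} of the candidate peak intensities.  With
#' \code{minSupport > 0}, retained points must additionally belong to a
#' spatial chain (single-linkage components, 7 px linking distance) of at
#' least \code{minSupport} points, which removes isolated bright speckle
#' survivors; the measurement pipeline uses \code{minSupport = 5}.
#'
#' Raising the threshold never increases the retained count, and the output
#' is always a subset of the input.
#'
#' When the source frame is supplied, the automatic threshold is
#' additionally capped at \code{median(frame) + 0.4 * (max peak -
#' median(frame))}: on clean frames nearly every candidate peak sits on a
#' bone ridge, so the mean + k*sd statistic alone lands above the maximum
#' and would reject everything, while the contrast cap keeps any peak well
#' separated from the background floor.
#'
#' @param points a \linkS4class{PointSet}.
#' @param threshold explicit intensity threshold, or NULL for mean + k*sd.
#' @param k multiplier for the automatic threshold (default 2).
#' @param minSupport minimum chain size (0 disables the chain rule).
#' @param frame optional source frame (matrix or
#'   \linkS4class{UltrasoundFrame}) for the contrast cap of the automatic
#'   threshold.
#' @return a \linkS4class{PointSet} (possibly empty).
#' @export
screenPeaks <- function(points, threshold = NULL, k = 2, minSupport = 0,
                        frame = NULL) {
  stopifnot(is(points, "PointSet"))
  ints <- points@intensities
  if (!length(ints))
    return(new("PointSet", coords = points@coords, intensities = ints))
  if (is.null(threshold)) {
    s <- if (length(ints) > 1L) stats::sd(ints) else 0
    threshold <- mean(ints) + k * s
    if (!is.null(frame)) {
      bg <- stats::median(asFrameMatrix(frame))
      threshold <- min(threshold, bg + 0.4 * (max(ints) - bg))
    }
  }
  keep <- ints >= threshold
  coords <- points@coords[keep, , drop = FALSE]
  ints <- ints[keep]
  if (minSupport > 0L && nrow(coords) > 0L) {
    comp <- peakComponents(coords)
    sizes <- tabulate(comp)
    ok <- sizes[comp] >= minSupport
    coords <- coords[ok, , drop = FALSE]
    ints <- ints[ok]
  }
  new("PointSet", coords = coords, intensities = ints)
}

# quadratic sub-pixel refinement of peak column positions along each row,
# using the 3-point neighborhood in the (preprocessed) frame
refinePeaksSubpixel <- function(coords, frameMat) {
  if (!nrow(coords)) return(coords)
  out <- coords * 1.0
  nc <- ncol(frameMat)
  for (i in seq_len(nrow(coords))) {
    r <- coords[i, 1]; cc <- coords[i, 2]
    if (cc <= 1 || cc >= nc) next
    y1 <- frameMat[r, cc - 1]; y2 <- frameMat[r, cc]; y3 <- frameMat[r, cc + 1]
    den <- y1 - 2 * y2 + y3
    if (den < 0) {
      delta <- 0.5 * (y1 - y3) / den
      out[i, 2] <- cc + max(-0.5, min(0.5, delta))
    }
  }
  out
}

# one-pass trimmed TLS: fit, drop gross outliers, refit
tlsTrim <- function(coords, maxResid = 2.5) {
  fit <- fitLineTLS(coords)
  res <- abs(linePointDistance(fit, coords))
  keep <- res <= max(maxResid, 3 * fit@rmsResidual)
  if (any(!keep) && sum(keep) >= 2L &&
      nrow(unique(coords[keep, , drop = FALSE])) >= 2L)
    fit <- fitLineTLS(coords[keep, , drop = FALSE])
  fit
}

#' Fit the bony acetabular roof line
#'
#' Fits a line to screened bone-surface points restricted to the region
#' spanned by the rim and lower-limb boxes, inflated by \code{margin} px.
#' Points within \code{excludeDist} px of the baseline are excluded first
#' (the iliac margin passes through the region at the rim and is parallel
#' to the baseline by construction).  Dynamic mode fits by trimmed total
#' least squares; static mode seeds with a Hough transform.
#'
#' @param frame preprocessed \linkS4class{UltrasoundFrame} or matrix (used
#'   for sub-pixel peak refinement), or NULL to skip refinement.
#' @param rimBox,iliumBox landmark boxes (rowMin, colMin, rowMax, colMax).
#' @param points screened \linkS4class{PointSet}.
#' @param baseline \linkS4class{LineModel} to exclude, or NULL.
#' @param mode "dynamic" or "static".
#' @param margin region inflation in px (default 10).
#' @param excludeDist baseline exclusion distance in px (default 2.5).
#' @return a \linkS4class{LineModel}, or NULL when fewer than 2 usable
#'   points remain (roof-fit failure; the frame is unusable).
#' @export
fitRoofLine <- function(frame, rimBox, iliumBox, points, baseline = NULL,
                        mode = c("dynamic", "static"), margin = 10,
                        excludeDist = 2.5) {
  mode <- match.arg(mode)
  stopifnot(is(points, "PointSet"))
  lo <- pmin(rimBox[1:2], iliumBox[1:2]) - margin
  hi <- pmax(rimBox[3:4], iliumBox[3:4]) + margin
  cd <- points@coords
  inRegion <- cd[, 1] >= lo[1] & cd[, 1] <= hi[1] &
              cd[, 2] >= lo[2] & cd[, 2] <= hi[2]
  cd <- cd[inRegion, , drop = FALSE]
  if (!is.null(baseline) && nrow(cd))
    cd <- cd[abs(linePointDistance(baseline, cd)) > excludeDist, ,
             drop = FALSE]
  if (nrow(unique(cd)) < 2L) return(NULL)
  if (!is.null(frame))
    cd <- refinePeaksSubpixel(cd, asFrameMatrix(frame))
  if (mode == "static") {
    seedFit <- houghFit(cd)
    inl <- abs(linePointDistance(seedFit, cd)) <= 2.5
    if (sum(inl) >= 2L &&
        nrow(unique(cd[inl, , drop = FALSE])) >= 2L)
      cd <- cd[inl, , drop = FALSE]
    tlsTrim(cd)
  } else {
    tlsTrim(cd)
  }
}

#' Center of a landmark bounding box
#'
#' @param det a \linkS4class{LandmarkDetection} or a length-4 box
#'   (rowMin, colMin, rowMax, colMax).
#' @return (row, col) center.
#' @examples
#' boxCenter(c(0, 0, 10, 10))
#' @export
boxCenter <- function(det) {
  b <- if (is(det, "LandmarkDetection")) det@box else det
  c((b[1] + b[3]) / 2, (b[2] + b[4]) / 2)
}

measureFailure <- function(reason, method, frameIndex = NA_integer_) {
  new("AlphaMeasurement", status = reason, alphaDeg = NA_real_,
      inclinationDeg = NA_real_, baseline = NULL, roofLine = NULL,
      iliacLine = NULL, method = method,
      frameIndex = as.integer(frameIndex))
}

defaultMeasureParams <- function(params = list()) {
  utils::modifyList(list(minSeparation = 3, screenK = 2, minSupport = 5,
    margin = 10, excludeDist = 2.5, thetaBin = 1, rhoBin = 1,
    subpixel = TRUE, rimRowMargin = 4), params)
}

#' Measure the Graf alpha-angle on one frame
#'
#' Orchestrates the full measurement: preprocess, per-row local-maxima
#' extraction, intensity screening, iliac-line fit (Hough-seeded in static
#' mode, trimmed TLS in dynamic mode), baseline construction through the
#' detected rim, roof-line fit in the landmark-spanned region, and the
#' angle computation.  All intermediate line models are retained in the
#' result.  Any stage failure yields a reason-coded failure result, never a
#' silent number.
#'
#' @param frame an \linkS4class{UltrasoundFrame} or numeric matrix.
#' @param detections list of \linkS4class{LandmarkDetection} (from
#'   \code{\link{detectLandmarks}} or an external detector).
#' @param mode "dynamic" (screened-maxima TLS) or "static" (Hough-seeded).
#' @param params named list of overrides: minSeparation, screenK,
#'   minSupport, margin, excludeDist, thetaBin, rhoBin, subpixel,
#'   rimRowMargin.
#' @param frameIndex 1-based frame index recorded in the result.
#' @return an \linkS4class{AlphaMeasurement}.
#' @examples
#' sc <- makeScene(70, 0)
#' fr <- renderFrame(sc, noiseConfig(speckleScale = 0, blurSigma = 0,
#'   shadowAttenuation = 0), seed = 1)
#' det <- detectLandmarks(fr$frame)
#' measureAlpha(fr$frame, det, mode = "dynamic")
#' @export
measureAlpha <- function(frame, detections, mode = c("dynamic", "static"),
                         params = list(), frameIndex = NA_integer_) {
  mode <- match.arg(mode)
  p <- defaultMeasureParams(params)
  labs <- vapply(detections, landmarkLabel, character(1))
  rimDet <- detections[labs == "acetabular_rim"]
  lowDet <- detections[labs == "ilium_lower_limb"]
  if (!length(rimDet))
    return(measureFailure("rim_not_detected", mode, frameIndex))
  if (!length(lowDet))
    return(measureFailure("lower_limb_not_detected", mode, frameIndex))
  rimDet <- rimDet[[1]]; lowDet <- lowDet[[1]]
  pp <- preprocessFrame(frame)
  ppm <- asFrameMatrix(pp)
  ps <- extractLocalMaxima(pp, "rows", p$minSeparation)
  sp <- screenPeaks(ps, k = p$screenK, minSupport = p$minSupport,
                    frame = ppm)
  if (nrow(sp@coords) < 2L)
    return(measureFailure("no_bone_surface", mode, frameIndex))
  rimAnchor <- boxCenter(rimDet)
  supp <- sp@coords[sp@coords[, 1] <= rimAnchor[1] - p$rimRowMargin, ,
                    drop = FALSE]
  if (nrow(unique(supp)) < 2L)
    return(measureFailure("iliac_fit_failed", mode, frameIndex))
  if (isTRUE(p$subpixel)) supp <- refinePeaksSubpixel(supp, ppm)
  iliacLine <- if (mode == "static") {
    seedFit <- houghFit(supp, p$thetaBin, p$rhoBin)
    inl <- abs(linePointDistance(seedFit, supp)) <= 2 * p$rhoBin
    if (sum(inl) >= 2L) tlsTrim(supp[inl, , drop = FALSE]) else seedFit
  } else {
    tlsTrim(supp)
  }
  # the rim lies on the iliac margin; project the (box-quantized) anchor
  # onto the fitted margin so the baseline coincides with it
  rimAnchor <- rimAnchor - lineNormal(iliacLine@theta) *
    drop(linePointDistance(iliacLine, rbind(rimAnchor)))
  baseline <- constructBaseline(iliacLine, rimAnchor)
  roofLine <- fitRoofLine(pp, boundingBox(rimDet), boundingBox(lowDet), sp,
                          baseline = baseline, mode = mode,
                          margin = p$margin, excludeDist = p$excludeDist)
  if (is.null(roofLine))
    return(measureFailure("roof_fit_failed", mode, frameIndex))
  alpha <- angleBetween(baseline, roofLine)
  new("AlphaMeasurement", status = "ok", alphaDeg = alpha,
      inclinationDeg = iliacInclination(iliacLine), baseline = baseline,
      roofLine = roofLine, iliacLine = iliacLine, method = mode,
      frameIndex = as.integer(frameIndex))
}
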