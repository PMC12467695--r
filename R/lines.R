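# Line geometry in the package convention: a line has direction
# d(theta) = (cos theta, sin theta) in (row, col) coordinates, theta in
# [0, 180) degrees from the vertical (column) axis, positive clockwise;
# unit normal n(theta) = (-sin theta, cos theta); line = {p : n . p = offset}.

DEG <- pi / 180

#' Round half away from zero
#'
#' Reporting convention for angles (1 decimal) and dimensionless effect
#' sizes (2 decimals).  \code{round()} rounds half to even; measurements
#' here are reported with half rounded away from zero instead.
#'
#' @param x numeric vector.
#' @param digits decimal places.
#' @return rounded numeric vector.
#' @export
roundHalfAway <- function(x, digits = 1L) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

lineDir <- function(theta) c(cos(theta * DEG), sin(theta * DEG))
lineNormal <- function(theta) c(-sin(theta * DEG), cos(theta * DEG))

# fold theta into [0, 180), flipping the offset sign when the direction flips
normalizeThetaOffset <- function(theta, offset) {
  theta <- theta %% 360
  if (theta >= 180) {
    theta <- theta - 180
    offset <- -offset
  }
  list(theta = theta, offset = offset)
}

#' Construct a LineModel
#'
#' @param theta direction in degrees (any value; folded into [0, 180)).
#' @param offset signed perpendicular distance from the origin, px.
#' @param rmsResidual RMS perpendicular residual, px.
#' @param nPoints supporting point count.
#' @return a \linkS4class{LineModel}.
#' @export
lineModel <- function(theta, offset, rmsResidual = 0, nPoints = 2L) {
  no <- normalizeThetaOffset(theta, offset)
  new("LineModel", theta = no$theta, offset = no$offset,
      rmsResidual = rmsResidual, nPoints = as.integer(nPoints))
}

#' Signed perpendicular distances from points to a line
#'
#' @param line a \linkS4class{LineModel}.
#' @param points n x 2 matrix of (row, col) coordinates.
#' @return numeric vector of signed distances (px).
#' @export
linePointDistance <- function(line, points) {
  points <- rbind(points)
  nrm <- lineNormal(line@theta)
  points %*% nrm - line@offset
}

# angle in [0, 90] between two segments given as 2x2 matrices (rows = ends)
segmentAngleDeg <- function(seg1, seg2) {
  v1 <- seg1[2, ] - seg1[1, ]
  v2 <- seg2[2, ] - seg2[1, ]
  c1 <- sum(v1 * v2) / sqrt(sum(v1^2) * sum(v2^2))
  a <- acos(pmin(1, pmax(-1, abs(c1)))) / DEG
  a
}

# separation of two theta values folded into [0, 90]
thetaSeparationDeg <- function(t1, t2) {
  d <- abs(t1 - t2) %% 180
  min(d, 180 - d)
}

#' Total-least-squares (orthogonal) line fit
#'
#' Fits a line minimizing the sum of squared perpendicular distances, via
#' the principal eigenvector of the 2 x 2 coordinate covariance.  This is
#' the right fit for near-vertical structures such as the iliac outer
#' margin, where ordinary row-on-col regression degenerates.
#'
#' @param points an n x 2 matrix of (row, col) coordinates or a
#'   \linkS4class{PointSet}.
#' @return a \linkS4class{LineModel}; \code{rmsResidual} is the RMS
#'   perpendicular distance of the points from the fitted line.
#' @export
setGeneric("fitLineTLS", function(points) standardGeneric("fitLineTLS"))

#' @rdname fitLineTLS
setMethod("fitLineTLS", "PointSet",
  function(points) fitLineTLS(points@coords))

#' @rdname fitLineTLS
setMethod("fitLineTLS", "matrix", function(points) {
  points <- points[stats::complete.cases(points), , drop = FALSE]
  if (nrow(unique(points)) < 2L)
    stop("fitLineTLS: need >= 2 distinct points")
  ctr <- colMeans(points)
  x <- sweep(points, 2, ctr)
  cv <- crossprod(x) / nrow(x)
  eg <- eigen(cv, symmetric = TRUE)
  v <- eg$vectors[, 1L]             # principal direction
  theta <- (atan2(v[2], v[1]) / DEG) %% 180
  if (theta == 180) theta <- 0
  nrm <- lineNormal(theta)
  offset <- sum(nrm * ctr)
  resid <- points %*% nrm - offset
  lineModel(theta, offset, rmsResidual = sqrt(mean(resid^2)),
            nPoints = nrow(points))
})

#' Hough-transform line fit with TLS refinement
#'
#' Accumulates points over a (theta, rho) grid, picks the accumulator
#' maximum (ties broken deterministically: smallest theta, then smallest
#' rho), and refines by total least squares on the inliers within
#' \code{2 * rhoBin} px of the winning bin's line.  rho is measured
#' relative to the point-set centroid, which makes the binning -- and hence
#' the selected inlier set -- exactly translation invariant.
#'
#' @param points an n x 2 matrix or \linkS4class{PointSet}.
#' @param thetaBin theta bin width, degrees (default 1).
#' @param rhoBin rho bin width, px (default 1).
#' @return a \linkS4class{LineModel} (offset in image coordinates).
#' @export
setGeneric("houghFit",
  function(points, thetaBin = 1, rhoBin = 1) standardGeneric("houghFit"))

#' @rdname houghFit
setMethod("houghFit", "PointSet",
  function(points, thetaBin, rhoBin) houghFit(points@coords, thetaBin, rhoBin))

#' @rdname houghFit
setMethod("houghFit", "matrix", function(points, thetaBin = 1, rhoBin = 1) {
  if (nrow(unique(points)) < 2L)
    stop("houghFit: need >= 2 distinct points")
  ctr <- colMeans(points)
  x <- sweep(points, 2, ctr)
  thetas <- seq(thetaBin / 2, 180 - thetaBin / 2, by = thetaBin)
  nrms <- rbind(-sin(thetas * DEG), cos(thetas * DEG))
  rho <- x %*% nrms                       # n x n_theta signed distances
  bins <- floor(rho / rhoBin)
  best <- c(count = -1L, it = NA_real_, bin = NA_real_)
  for (it in seq_along(thetas)) {
    tb <- table(bins[, it])
    cnt <- max(tb)
    if (cnt > best["count"]) {
      cand <- as.numeric(names(tb)[tb == cnt])
      best <- c(count = cnt, it = it, bin = min(cand))
    }
  }
  it <- best[["it"]]
  rho0 <- (best[["bin"]] + 0.5) * rhoBin
  inl <- abs(rho[, it] - rho0) <= 2 * rhoBin
  if (sum(inl) >= 2L && nrow(unique(points[inl, , drop = FALSE])) >= 2L) {
    fitLineTLS(points[inl, , drop = FALSE])
  } else {
    lineModel(thetas[it], sum(lineNormal(thetas[it]) * ctr) + rho0,
              nPoints = max(2L, sum(inl)))
  }
})

#' Baseline parallel to the iliac margin through the acetabular rim
#'
#' @param iliacLine \linkS4class{LineModel} of the iliac outer margin.
#' @param rimAnchor (row, col) anchor, usually the rim box center.
#' @return a \linkS4class{LineModel} with the same theta, passing through
#'   the anchor.
#' @export
constructBaseline <- function(iliacLine, rimAnchor) {
  stopifnot(is(iliacLine, "LineModel"), length(rimAnchor) == 2L)
  nrm <- lineNormal(iliacLine@theta)
  lineModel(iliacLine@theta, sum(nrm * rimAnchor),
            rmsResidual = iliacLine@rmsResidual,
            nPoints = iliacLine@nPoints)
}

#' Angle between two lines (Graf alpha convention)
#'
#' Reports the inter-line angle folded into [0, 90]: the Graf alpha opens
#' caudally from the baseline toward the bony roof and never exceeds a
#' right angle for physically meaningful geometry.  Symmetric in its
#' arguments.
#'
#' @param l1,l2 \linkS4class{LineModel} objects.
#' @return angle in degrees in [0, 90].
#' @export
angleBetween <- function(l1, l2) {
  stopifnot(is(l1, "LineModel"), is(l2, "LineModel"))
  thetaSeparationDeg(l1@theta, l2@theta)
}

#' Signed iliac inclination relative to the vertical image axis
#'
#' Folds the line direction into [-90, 90): 0 for a perfectly vertical
#' iliac margin, positive clockwise; e.g. theta = 175 maps to -5.
#'
#' @param iliacLine a \linkS4class{LineModel}.
#' @return inclination in degrees in [-90, 90).
#' @export
iliacInclination <- function(iliacLine) {
  stopifnot(is(iliacLine, "LineModel"))
  ((iliacLine@theta + 90) %% 180) - 90
}
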