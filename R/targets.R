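# Phantom-validation experiment: the package's end-to-end benchmark.
# Forty independent diagnostic-quality frames of the 70-degree phantom at
# moderate noise are pushed through the dynamic pipeline; the summary is
# the per-frame success rate and the mean absolute alpha error against the
# known reference.

#' Run the synthetic phantom validation experiment
#'
#' Generates \code{nFrames} diagnostic-quality frames of a phantom scene
#' with true alpha \code{alphaTrue} (default 70 degrees), iliac inclination
#' drawn uniformly in \code{inclinationRange}, and moderate noise (speckle
#' 0.2, blur 1.0 px by default), then runs the dynamic measurement pipeline
#' with the default quality gates and summarizes accuracy and success rate
#' against the known reference.
#'
#' @param seed integer master seed; frame k is rendered with seed
#'   \code{seed + k}, and the inclination draws use \code{seed} itself.
#' @param nFrames number of frames (default 40).
#' @param alphaTrue reference alpha-angle in degrees (default 70).
#' @param inclinationRange range of the uniform inclination draw, degrees.
#' @param noise a \linkS4class{NoiseConfig} (default: speckle 0.2, blur
#'   1.0 px, shadow 0.3).
#' @param gates quality gates (default \code{\link{qualityGates}()}).
#' @return list with elements \code{mae} (mean absolute error over
#'   assessed frames, degrees), \code{successPct} (percent of frames with
#'   a gated non-failure measurement), \code{n}, \code{successLabel}
#'   ("k/n"), \code{alphas} (per-frame measured alpha, NA on failure), and
#'   \code{result} (the full \linkS4class{SequenceResult}).
#' @examples
#' \donttest{
#' ex <- phantomValidation(seed = 1, nFrames = 5)
#' ex$mae
#' }
#' @export
phantomValidation <- function(seed, nFrames = 40L, alphaTrue = 70,
                              inclinationRange = c(-3, 3),
                              noise = noiseConfig(), gates = qualityGates()) {
  seed <- as.integer(seed)
  set.seed(seed)
  incl <- stats::runif(nFrames, inclinationRange[1], inclinationRange[2])
  frames <- vector("list", nFrames)
  for (k in seq_len(nFrames)) {
    sc <- makeScene(alphaTrue, incl[k])
    frames[[k]] <- renderFrame(sc, noise, seed = seed + k)$frame
  }
  res <- runSequence(frames, gates = gates, mode = "dynamic")
  ok <- vapply(res@reports, isDiagnostic, logical(1))
  alphas <- vapply(res@measurements, alphaDeg, numeric(1))
  sr <- successRate(ok)
  mae <- if (any(ok)) meanAbsoluteError(alphas[ok], alphaTrue) else NA_real_
  list(mae = mae, successPct = 100 * sr$rate, n = nFrames,
       successLabel = sr$label, alphas = alphas, result = res)
}

#' Arithmetic of the reported agreement summaries
#'
#' Recomputes limits of agreement from (bias, SD) summary pairs for the
#' three measurement arms of a phantom comparison (dynamic video, manual,
#' static image), plus Cohen's f from an eta-squared, at the package's
#' reporting precision (one decimal for angles, two for dimensionless).
#'
#' @param arms data.frame with columns \code{arm}, \code{bias}, \code{sd}.
#' @param eta2 eta-squared value for the Cohen's f conversion.
#' @param z limits-of-agreement multiplier.
#' @return list with a per-arm data.frame of rounded LoA and
#'   \code{cohensF}.
#' @export
agreementArithmetic <- function(arms = data.frame(
    arm = c("dynamic", "manual", "static"),
    bias = c(-0.8, -6.0, -0.7), sd = c(2.4, 4.7, 10.4)),
    eta2 = 0.291, z = 1.96) {
  loa <- t(mapply(function(b, s) loaFromBiasSd(b, s, z), arms$bias, arms$sd))
  out <- data.frame(arm = arms$arm, bias = arms$bias, sd = arms$sd,
                    loaLower = roundHalfAway(loa[, 1], 1L),
                    loaUpper = roundHalfAway(loa[, 2], 1L))
  list(loa = out, cohensF = roundHalfAway(cohensFFromEta2(eta2), 2L))
}
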