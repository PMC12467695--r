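# Shared fixtures: all synthetic frames are generated in code at test time.

noiselessConfig <- function()
  noiseConfig(speckleScale = 0, blurSigma = 0, shadowAttenuation = 0)

blurOnlyConfig <- function()
  noiseConfig(speckleScale = 0, blurSigma = 1, shadowAttenuation = 0)

renderPhantom <- function(alpha = 70, incl = 0, noise = noiseConfig(),
                          seed = 1) {
  renderFrame(makeScene(alpha, incl), noise, seed = seed)
}

# brute-force oracle for the TLS line fit: two-stage grid search over theta
# (coarse full sweep, then fine local refinement); for each candidate theta
# the optimal offset is the mean normal projection, and the objective is
# the RMS perpendicular residual
gridSearchLine <- function(pts, coarse = 0.5, fine = 0.02) {
  rmsAt <- function(th) {
    nrm <- c(-sin(th * pi / 180), cos(th * pi / 180))
    proj <- pts %*% nrm
    off <- mean(proj)
    sqrt(mean((proj - off)^2))
  }
  thetas <- seq(0, 180 - coarse, by = coarse)
  r <- vapply(thetas, rmsAt, numeric(1))
  t0 <- thetas[which.min(r)]
  thetas2 <- seq(t0 - coarse, t0 + coarse, by = fine)
  r2 <- vapply(thetas2, rmsAt, numeric(1))
  tBest <- thetas2[which.min(r2)] %% 180
  nrm <- c(-sin(tBest * pi / 180), cos(tBest * pi / 180))
  list(theta = tBest, offset = mean(pts %*% nrm), rms = min(r2))
}

# independent ICC(2,1) oracle: mean squares from stats::aov on the long
# format, plugged into the variance-components form
iccOracleAov <- function(m) {
  n <- nrow(m); k <- ncol(m)
  long <- data.frame(y = as.vector(m),
                     subj = factor(rep(seq_len(n), times = k)),
                     rater = factor(rep(seq_len(k), each = n)))
  tab <- summary(stats::aov(y ~ subj + rater, data = long))[[1]]
  msr <- tab["subj", "Mean Sq"]
  msc <- tab["rater", "Mean Sq"]
  mse <- tab["Residuals", "Mean Sq"]
  (msr - mse) / (msr + (k - 1) * mse + k * (msc - mse) / n)
}

# nearest-neighbour rotation of a frame matrix about a center (test-side
# resampler, independent of the renderer)
rotateFrameNN <- function(m, deltaDeg, center, fill = 0) {
  d <- deltaDeg * pi / 180
  out <- matrix(fill, nrow(m), ncol(m))
  idx <- cbind(rep(seq_len(nrow(m)), ncol(m)),
               rep(seq_len(ncol(m)), each = nrow(m)))
  rel <- sweep(idx, 2, center)
  # inverse map: source = center + R(-delta) (target - center)
  src <- cbind(cos(d) * rel[, 1] + sin(d) * rel[, 2],
               -sin(d) * rel[, 1] + cos(d) * rel[, 2])
  src <- round(sweep(src, 2, center, "+"))
  ok <- src[, 1] >= 1 & src[, 1] <= nrow(m) &
        src[, 2] >= 1 & src[, 2] <= ncol(m)
  out[idx[ok, , drop = FALSE]] <- m[src[ok, , drop = FALSE]]
  out
}

shiftFrame <- function(m, dr, dc, fill) {
  out <- matrix(fill, nrow(m), ncol(m))
  srcR <- seq_len(nrow(m)) - dr
  srcC <- seq_len(ncol(m)) - dc
  okR <- srcR >= 1 & srcR <= nrow(m)
  okC <- srcC >= 1 & srcC <= ncol(m)
  out[which(okR), which(okC)] <- m[srcR[okR], srcC[okC]]
  out
}
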