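# shared fixtures built in code

# disc mask/image helpers
discMask <- function(h, w, cy, cx, r) {
  yy <- matrix(rep(seq_len(h), w), h, w)
  xx <- matrix(rep(seq_len(w), each = h), h, w)
  (yy - cy)^2 + (xx - cx)^2 <= r^2
}

# a small labelled mask built directly from discs (bypasses segmentation)
discLabeledMask <- function(h, w, centers, radii, intensity = NULL) {
  mask <- matrix(0L, h, w)
  for (i in seq_len(nrow(centers)))
    mask[discMask(h, w, centers[i, 1], centers[i, 2], radii[i])] <- i
  if (is.null(intensity)) intensity <- matrix(100, h, w)
  new("LabeledMask", mask = mask,
      objects = icdQuant:::.objectStats(mask, intensity))
}

# brute-force granularity oracle: explicit double loop over grid blocks
granularityOracle <- function(channel, roi, blockPx = 4, minCoverage = 0.5) {
  idx <- which(roi, arr.ind = TRUE)
  y0 <- min(idx[, 1]); y1 <- max(idx[, 1])
  x0 <- min(idx[, 2]); x1 <- max(idx[, 2])
  means <- c()
  for (by in seq(y0, y1, by = blockPx)) {
    for (bx in seq(x0, x1, by = blockPx)) {
      ys <- by:min(by + blockPx - 1, nrow(roi))
      xs <- bx:min(bx + blockPx - 1, ncol(roi))
      sel <- roi[ys, xs, drop = FALSE]
      if (sum(sel) >= minCoverage * blockPx^2)
        means <- c(means, mean(channel[ys, xs, drop = FALSE][sel]))
    }
  }
  if (length(means) < 2) return(NA_real_)
  stats::sd(means) / mean(channel[roi])
}
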