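#' Granularity score of a region of interest
#'
#' The per-cell texture statistic used to score punctate versus diffuse
#' biosensor distribution (CALR-GFP aggregates, quinacrine-stained ATP
#' vesicles): the standard deviation of the mean intensities of groups of
#' adjacent pixels (non-overlapping square blocks) within the ROI, divided
#' by the mean intensity over the whole ROI. A perfectly uniform ROI
#' scores 0; the score is invariant under multiplication of all
#' intensities by a positive constant.
#'
#' Blocks form a square grid of side \code{blockPx} anchored at the origin
#' of the ROI bounding box. A block enters the statistic only if at least
#' \code{minCoverage} of its pixels lie inside the ROI; the block mean is
#' taken over ROI pixels only. The SD uses the sample (n-1) denominator.
#'
#' @param channel 2-D intensity matrix
#' @param roi logical matrix of the same shape (the cytoplasmic ROI)
#' @param blockPx block side length, px (>= 2)
#' @param minCoverage minimum fraction of a block covered by the ROI
#' @return the score (dimensionless, >= 0), or \code{NA} with attribute
#'   \code{reason} when undefined (fewer than 2 valid blocks, or ROI mean
#'   0); such cells are excluded and logged by \code{\link{measureField}}
#' @examples
#' roi <- matrix(TRUE, 4, 8)
#' img <- cbind(matrix(10, 4, 4), matrix(30, 4, 4))
#' granularityScore(img, roi)  # sd(c(10,30))/20 = 0.7071
#' @export
granularityScore <- function(channel, roi, blockPx = 4, minCoverage = 0.5) {
  stopifnot(is.matrix(channel), is.logical(roi),
            identical(dim(channel), dim(roi)))
  if (blockPx < 2) stop("blockPx must be >= 2")
  idx <- which(roi)
  if (length(idx) == 0) stop("empty ROI")
  h <- nrow(roi)
  yy <- ((idx - 1) %% h) + 1
  xx <- ((idx - 1) %/% h) + 1
  y0 <- min(yy); x0 <- min(xx)
  bi <- (yy - y0) %/% blockPx
  bj <- (xx - x0) %/% blockPx
  bid <- bi * (max(bj) + 1L) + bj + 1L
  cnt <- rowsum(rep(1, length(idx)), bid)
  sums <- rowsum(channel[idx], bid)
  valid <- cnt >= minCoverage * blockPx^2
  if (sum(valid) < 2) {
    return(structure(NA_real_, reason = "fewer than 2 valid blocks"))
  }
  roiMean <- mean(channel[idx])
  if (roiMean == 0) return(structure(NA_real_, reason = "ROI mean is zero"))
  stats::sd(sums[valid] / cnt[valid]) / roiMean
}

#' Mean intensity over a nuclear mask
#'
#' Arithmetic mean of a channel over the nucleus, the readout used for
#' nuclear HMGB1-GFP retention.
#'
#' @param channel 2-D intensity matrix
#' @param nucleus logical mask of the nucleus
#' @return mean intensity
#' @export
nuclearMeanIntensity <- function(channel, nucleus) {
  stopifnot(is.matrix(channel), identical(dim(channel), dim(nucleus)))
  if (!any(nucleus)) stop("empty nucleus mask")
  mean(channel[nucleus])
}

#' Mean intensity over a whole cell (nucleus plus cytoplasm)
#'
#' The readout used for the whole-cell MX1-GFP interferon reporter.
#'
#' @param channel 2-D intensity matrix
#' @param nucleus,cytoplasm logical masks
#' @return mean intensity over the union mask
#' @export
cellMeanIntensity <- function(channel, nucleus, cytoplasm) {
  stopifnot(is.matrix(channel), identical(dim(channel), dim(nucleus)),
            identical(dim(channel), dim(cytoplasm)))
  u <- nucleus | cytoplasm
  if (!any(u)) stop("empty nucleus/cytoplasm union")
  mean(channel[u])
}

#' Measure per-cell records for one view field
#'
#' Computes, for every segmented cell, the assay-appropriate biosensor
#' feature (cytoplasmic granularity for CALR-GFP and quinacrine, nuclear
#' mean for HMGB1-GFP, whole-cell mean for MX1-GFP), along with nucleus
#' area, mean Hoechst, mean PI over the nucleus and a live/dead flag
#' (live when nuclear PI stays below \code{piThreshold}).
#'
#' The biosensor and PI channels are background-corrected by subtracting
#' the per-image median (floored at 0) before feature computation, which
#' makes SD/mean scores and the PI gate comparable across fields; set
#' \code{backgroundSubtract = FALSE} to measure raw intensities.
#'
#' @param field a \linkS4class{FieldImage} with channels Hoechst, GFP, PI
#' @param rois a \linkS4class{CellROIs} for the field
#' @param assay one of \code{"CALR_GFP"}, \code{"QUINACRINE"},
#'   \code{"HMGB1_GFP"}, \code{"MX1_GFP"}
#' @param piThreshold nuclear PI mean (background-corrected counts) above
#'   which a cell is flagged dead
#' @param blockPx,minCoverage granularity parameters, see
#'   \code{\link{granularityScore}}
#' @param backgroundSubtract subtract the per-image median background from
#'   the GFP and PI channels
#' @return data.frame with one row per cell: \code{cell_id}, \code{well},
#'   \code{field}, \code{nucleus_area_px}, \code{nucleus_mean_hoechst},
#'   \code{granularity_score}, \code{nuclear_biosensor_mean},
#'   \code{cell_mean_gfp}, \code{pi_mean}, \code{live}, \code{feature}
#'   (the assay feature), \code{qc_ok}, \code{qc_reason}
#' @export
measureField <- function(field, rois, assay, piThreshold = 500,
                         blockPx = 4, minCoverage = 0.5,
                         backgroundSubtract = TRUE) {
  stopifnot(is(field, "FieldImage"), is(rois, "CellROIs"))
  .checkAssay(assay)
  hoechst <- getChannel(field, "Hoechst")
  gfp <- getChannel(field, "GFP")
  pi_ch <- getChannel(field, "PI")
  if (backgroundSubtract) {
    gfp <- pmax(gfp - stats::median(gfp), 0)
    pi_ch <- pmax(pi_ch - stats::median(pi_ch), 0)
  }
  labels <- rois@labels
  n <- length(labels)
  rec <- data.frame(
    cell_id = labels, well = rep(field@well, n), field = rep(field@field, n),
    nucleus_area_px = rep(NA_integer_, n),
    nucleus_mean_hoechst = rep(NA_real_, n),
    granularity_score = rep(NA_real_, n),
    nuclear_biosensor_mean = rep(NA_real_, n),
    cell_mean_gfp = rep(NA_real_, n), pi_mean = rep(NA_real_, n),
    live = rep(NA, n), feature = rep(NA_real_, n),
    qc_ok = rep(TRUE, n), qc_reason = rep("", n))
  if (n == 0) return(rec)
  for (i in seq_len(n)) {
    k <- labels[i]
    nm <- rois@nuclei == k
    cm <- rois@cytoplasm == k
    rec$nucleus_area_px[i] <- sum(nm)
    rec$nucleus_mean_hoechst[i] <- mean(hoechst[nm])
    rec$pi_mean[i] <- mean(pi_ch[nm])
    rec$live[i] <- rec$pi_mean[i] < piThreshold
    feat <- NA_real_
    if (assay %in% c("CALR_GFP", "QUINACRINE")) {
      if (!any(cm)) {
        rec$qc_ok[i] <- FALSE
        rec$qc_reason[i] <- "empty cytoplasm ROI"
      } else {
        g <- granularityScore(gfp, cm, blockPx, minCoverage)
        if (is.na(g)) {
          rec$qc_ok[i] <- FALSE
          rec$qc_reason[i] <- attr(g, "reason")
        } else feat <- g
        rec$granularity_score[i] <- as.numeric(g)
      }
    } else if (assay == "HMGB1_GFP") {
      feat <- nuclearMeanIntensity(gfp, nm)
      rec$nuclear_biosensor_mean[i] <- feat
    } else {
      feat <- cellMeanIntensity(gfp, nm, cm)
      rec$cell_mean_gfp[i] <- feat
    }
    rec$feature[i] <- feat
  }
  rec
}
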