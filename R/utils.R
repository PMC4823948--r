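# internal helpers shared across modules

.assayLevels <- c("CALR_GFP", "QUINACRINE", "HMGB1_GFP", "MX1_GFP")

.checkAssay <- function(assay) {
  if (length(assay) != 1 || !assay %in% .assayLevels)
    stop("unknown assay '", paste(assay, collapse = ","),
         "'; must be one of ", paste(.assayLevels, collapse = ", "))
  assay
}

# coordinate grids for a H x W raster (row = y, col = x), pixel-centred
.gridY <- function(h, w) matrix(rep(seq_len(h), w), h, w)
.gridX <- function(h, w) matrix(rep(seq_len(w), each = h), h, w)

# relabel a label matrix so nonzero labels are contiguous 1..K;
# returns list(mask, map) where map[old] = new (0 for dropped labels)
.relabel <- function(mask, keep) {
  k <- max(mask, 0)
  map <- integer(k)
  map[keep] <- seq_along(keep)
  out <- mask
  nz <- out > 0
  out[nz] <- map[out[nz]]
  list(mask = out, map = map)
}

# per-label area, centroid and mean intensity over a raster
.objectStats <- function(mask, intensity) {
  k <- max(mask, 0)
  if (k == 0)
    return(data.frame(label = integer(0), y = numeric(0), x = numeric(0),
                      area_px = integer(0), mean_intensity = numeric(0)))
  idx <- which(mask > 0)
  lab <- mask[idx]
  h <- nrow(mask)
  yy <- ((idx - 1) %% h) + 1
  xx <- ((idx - 1) %/% h) + 1
  area <- tabulate(lab, nbins = k)
  data.frame(
    label = seq_len(k),
    y = as.vector(rowsum(as.numeric(yy), lab)) / area,
    x = as.vector(rowsum(as.numeric(xx), lab)) / area,
    area_px = as.integer(area),
    mean_intensity = as.vector(rowsum(as.numeric(intensity[idx]), lab)) / area)
}

.stars <- function(p) {
  ifelse(p < 0.001, "***", ifelse(p < 0.01, "**", ifelse(p < 0.05, "*", "")))
}
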