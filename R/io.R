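#' Write a view field as a multi-page 16-bit TIFF
#'
#' One page per channel, in channel order, plus a sidecar JSON
#' (\code{<file>.json}) recording the channel names and well/field
#' metadata so the field round-trips through
#' \code{\link{readFieldTIFF}}.
#'
#' @param field a \linkS4class{FieldImage} (intensities in 16-bit counts)
#' @param file output path (\code{.tif})
#' @return the file path, invisibly
#' @export
writeFieldTIFF <- function(field, file) {
  stopifnot(is(field, "FieldImage"))
  pages <- lapply(field@channels, function(m) {
    n <- pmin(pmax(round(m), 0), 65535)
    pmin((n + 0.1) / 65535, 1)  # robust to floor- or round-quantization
  })
  tiff::writeTIFF(pages, file, bits.per.sample = 16L)
  jsonlite::write_json(
    list(channels = names(field@channels), well = field@well,
         field = field@field),
    paste0(file, ".json"), auto_unbox = TRUE)
  invisible(file)
}

#' Read a view field written by \code{\link{writeFieldTIFF}}
#'
#' @param file TIFF path; the sidecar \code{<file>.json} supplies channel
#'   names and metadata when present
#' @param channelNames channel names to use when no sidecar exists
#' @return a \linkS4class{FieldImage} with intensities in 16-bit counts
#' @export
readFieldTIFF <- function(file, channelNames = NULL) {
  pages <- tiff::readTIFF(file, all = TRUE)
  pages <- lapply(pages, function(p) {
    if (length(dim(p)) == 3) p <- p[, , 1]
    round(p * 65535)
  })
  well <- NA_character_; fld <- NA_integer_
  side <- paste0(file, ".json")
  if (file.exists(side)) {
    meta <- jsonlite::read_json(side, simplifyVector = TRUE)
    channelNames <- meta$channels
    well <- meta$well; fld <- as.integer(meta$field)
  }
  if (is.null(channelNames))
    channelNames <- paste0("ch", seq_along(pages))
  names(pages) <- channelNames
  new("FieldImage", channels = pages, well = well, field = fld)
}

#' Write an RGB tissue image as 8-bit PNG
#'
#' @param rgb H x W x 3 array of integers 0--255 (as produced by
#'   \code{\link{generateHETissue}})
#' @param file output path
#' @return the file path, invisibly
#' @export
writeTissuePNG <- function(rgb, file) {
  png::writePNG(rgb / 255, file)
  invisible(file)
}

#' Read an 8-bit RGB tissue image (PNG)
#'
#' @param file path
#' @return H x W x 3 array of integers 0--255
#' @export
readTissuePNG <- function(file) {
  x <- png::readPNG(file)
  round(x[, , 1:3] * 255)
}

#' Read a plate layout CSV
#'
#' Expected columns: \code{well}, \code{role} (\code{neg}, \code{pos} or
#' \code{treated}), \code{treatment}, \code{dose}.
#'
#' @param file CSV path
#' @return layout data.frame
#' @export
readPlateLayout <- function(file) {
  layout <- utils::read.csv(file, stringsAsFactors = FALSE)
  need <- c("well", "role", "dose")
  miss <- setdiff(need, names(layout))
  if (length(miss))
    stop("layout is missing column(s): ", paste(miss, collapse = ", "))
  layout
}
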