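#' Specification of a synthetic HE-stained tissue image
#'
#' Parameters of the hematoxylin--eosin tissue generator: a circular
#' necrotic region of requested area fraction where hematoxylin density is
#' low and eosin density high (the HE de-coloration signature of
#' necrosis), optional leukocyte puncta (small, strongly
#' hematoxylin-dense blobs) inside the necrotic region, and Gaussian noise
#' on the density maps.
#'
#' @param imageShape image height and width in pixels
#' @param necroticFraction requested necrotic area fraction in [0, 1)
#' @param hIn,hOut hematoxylin OD density inside/outside the necrotic
#'   region
#' @param eIn,eOut eosin OD density inside/outside the necrotic region
#' @param leukocyteCount number of leukocyte puncta to plant
#' @param leukocyteRadius punctum radius, px
#' @param leukocyteH extra hematoxylin density of a punctum
#' @param noiseSd Gaussian noise SD on the density maps
#' @param seed integer seed
#' @return an object of class \code{TissueSpec}
#' @export
tissueSpec <- function(imageShape = c(256L, 256L), necroticFraction = 0.25,
                       hIn = 0.15, hOut = 0.7, eIn = 0.75, eOut = 0.45,
                       leukocyteCount = 0L, leukocyteRadius = 2,
                       leukocyteH = 2, noiseSd = 0.02, seed = 1L) {
  if (necroticFraction < 0 || necroticFraction >= 1)
    stop("necroticFraction must lie in [0, 1)")
  if (leukocyteCount < 0) stop("leukocyteCount must be >= 0")
  structure(list(imageShape = as.integer(imageShape),
                 necroticFraction = necroticFraction,
                 hIn = hIn, hOut = hOut, eIn = eIn, eOut = eOut,
                 leukocyteCount = as.integer(leukocyteCount),
                 leukocyteRadius = leukocyteRadius, leukocyteH = leukocyteH,
                 noiseSd = noiseSd, seed = as.integer(seed)),
            class = "TissueSpec")
}

#' Generate a synthetic HE-stained tissue image with ground truth
#'
#' Builds hematoxylin and eosin density maps (uniform tissue with a
#' central necrotic disc of the requested area fraction and planted
#' leukocyte puncta), then composes an 8-bit RGB image by Beer--Lambert
#' absorption through the standard HE stain vectors (see
#' \code{\link{composeHE}}).
#'
#' @param spec a \code{\link{tissueSpec}}
#' @param vectors 3 x 2 stain vector matrix, columns hematoxylin and eosin
#' @return list with \code{rgb} (H x W x 3 array of integers 0--255) and
#'   \code{truth}: realized \code{necroticFraction} (pixel-exact),
#'   \code{necroticMask}, leukocyte \code{centers} data.frame, and the
#'   true \code{densityH}/\code{densityE} maps
#' @export
generateHETissue <- function(spec, vectors = heStainVectors()) {
  stopifnot(inherits(spec, "TissueSpec"))
  withr::with_seed(spec$seed, {
    h <- spec$imageShape[1]; w <- spec$imageShape[2]
    yy <- .gridY(h, w); xx <- .gridX(h, w)
    if (spec$necroticFraction > 0) {
      r <- sqrt(spec$necroticFraction * h * w / pi)
      cy <- h / 2 + 0.5; cx <- w / 2 + 0.5
      necro <- (yy - cy)^2 + (xx - cx)^2 <= r^2
    } else {
      necro <- matrix(FALSE, h, w)
    }
    realized <- mean(necro)
    dh <- matrix(spec$hOut, h, w); de <- matrix(spec$eOut, h, w)
    dh[necro] <- spec$hIn; de[necro] <- spec$eIn

    centers <- data.frame(y = numeric(0), x = numeric(0))
    if (spec$leukocyteCount > 0) {
      region <- if (any(necro)) which(necro) else seq_len(h * w)
      # keep puncta separated so each forms its own blob
      ry <- ((region - 1) %% h) + 1
      rx <- ((region - 1) %/% h) + 1
      ok <- ry > 3 & ry < h - 3 & rx > 3 & rx < w - 3
      region <- region[ok]; ry <- ry[ok]; rx <- rx[ok]
      sel <- integer(0)
      ord <- sample.int(length(region))
      minSep <- (4 * spec$leukocyteRadius)^2
      for (j in ord) {
        if (length(sel) >= spec$leukocyteCount) break
        if (length(sel) == 0 ||
            all((ry[sel] - ry[j])^2 + (rx[sel] - rx[j])^2 > minSep))
          sel <- c(sel, j)
      }
      if (length(sel) < spec$leukocyteCount)
        stop("could not place ", spec$leukocyteCount,
             " separated leukocyte puncta in the region")
      centers <- data.frame(y = ry[sel], x = rx[sel])
      for (j in seq_len(nrow(centers))) {
        m <- (yy - centers$y[j])^2 + (xx - centers$x[j])^2 <=
          spec$leukocyteRadius^2
        dh[m] <- dh[m] + spec$leukocyteH
      }
    }
    dh <- pmax(dh + matrix(stats::rnorm(h * w, 0, spec$noiseSd), h, w), 0)
    de <- pmax(de + matrix(stats::rnorm(h * w, 0, spec$noiseSd), h, w), 0)
    list(rgb = composeHE(dh, de, vectors),
         truth = list(necroticFraction = realized, necroticMask = necro,
                      centers = centers, densityH = dh, densityE = de))
  })
}
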