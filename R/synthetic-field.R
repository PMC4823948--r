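#' Specification of a synthetic microscopy view field
#'
#' Bundles the parameters of the synthetic field generator: cell number and
#' geometry, the biosensor assay being emulated, the fraction of cells in
#' the "responder" (treated-phenotype) state, granule rendering parameters,
#' intensity levels and the noise model. All randomness downstream of a
#' spec flows from its single integer \code{seed}.
#'
#' Intensity levels are expected photon counts on a 16-bit scale. The
#' default geometry (208 x 208 px fields of 50 cells with 6 px nuclei,
#' separated so that neighbouring cytoplasm regions do not touch) is a
#' scaled-down rendering of a wide-field 20x view; densities per field are
#' free parameters of the generator, not measured values.
#'
#' @param nCells number of cells to place (>= 0)
#' @param imageShape image height and width in pixels
#' @param nucleusRadius mean and SD of the nuclear radius, px
#' @param ringWidth cytoplasmic ring width, px
#' @param cellGap minimum gap between nucleus boundaries, px; the default
#'   keeps cytoplasm regions of neighbouring cells from overlapping so
#'   per-cell phenotypes render without crosstalk
#' @param assay one of \code{"CALR_GFP"}, \code{"QUINACRINE"},
#'   \code{"HMGB1_GFP"}, \code{"MX1_GFP"}
#' @param responderFraction fraction of cells in the responder state for
#'   the chosen assay (granular CALR-GFP; quinacrine vesicles depleted;
#'   nuclear HMGB1 released; MX1 reporter induced)
#' @param deadFraction fraction of PI-positive (dead) cells
#' @param granuleCount granules rendered per granule-bearing cell
#'   (default 8 for CALR-GFP aggregates, 30 for quinacrine vesicles)
#' @param granuleSigma Gaussian spot width of a granule, px
#' @param granuleMass integrated intensity of one granule, counts
#' @param nDebris number of small sub-nuclear debris specks to plant in the
#'   Hoechst channel
#' @param intensity named list overriding intensity defaults (see
#'   \code{Details})
#' @param readSd additive Gaussian read-noise SD, counts
#' @param seed integer seed fixing the output bit-exactly
#'
#' @details Intensity defaults: \code{background} 100, \code{nucleusLevel}
#' (Hoechst) 3000, \code{cytoplasmLevel} (diffuse biosensor) 800,
#' \code{nuclearBiosensorLevel} (retained HMGB1-GFP) 2000,
#' \code{hmgb1ReleasedFactor} 0.2, \code{mx1Baseline} 300,
#' \code{mx1Induced} 3000, \code{piDeadLevel} 6000, \code{nucleusGfpLevel}
#' 300, \code{cellCV} 0.1 (per-cell lognormal expression variability),
#' \code{deadHoechstFactor} 2.2 and \code{deadShrinkFactor} 0.7
#' (condensed, brighter nuclei of dead cells), \code{debrisLevel} 2500.
#'
#' @return an object of class \code{FieldSpec}
#' @seealso \code{\link{generateField}}, \code{\link{generatePlate}}
#' @export
fieldSpec <- function(nCells = 50L, imageShape = c(208L, 208L),
                      nucleusRadius = c(6, 0.8), ringWidth = 4, cellGap = 6,
                      assay = "CALR_GFP", responderFraction = 0,
                      deadFraction = 0.1,
                      granuleCount = NULL, granuleSigma = NULL,
                      granuleMass = NULL, nDebris = 0L,
                      intensity = list(), readSd = 10, seed = 1L) {
  .checkAssay(assay)
  if (nCells < 0) stop("nCells must be >= 0")
  if (responderFraction < 0 || responderFraction > 1)
    stop("responderFraction must lie in [0, 1]")
  if (deadFraction < 0 || deadFraction > 1)
    stop("deadFraction must lie in [0, 1]")
  if (is.null(granuleCount))
    granuleCount <- if (assay == "QUINACRINE") 30L else 8L
  if (is.null(granuleSigma))
    granuleSigma <- if (assay == "QUINACRINE") 1.2 else 1.5
  if (is.null(granuleMass))
    granuleMass <- if (assay == "QUINACRINE") 6000 else 20000
  defaults <- list(background = 100, nucleusLevel = 3000,
                   cytoplasmLevel = 800, nuclearBiosensorLevel = 2000,
                   hmgb1ReleasedFactor = 0.2, mx1Baseline = 300,
                   mx1Induced = 3000, piDeadLevel = 6000,
                   nucleusGfpLevel = 300, cellCV = 0.1,
                   deadHoechstFactor = 2.2, deadShrinkFactor = 0.7,
                   debrisLevel = 2500)
  bad <- setdiff(names(intensity), names(defaults))
  if (length(bad)) stop("unknown intensity parameter(s): ",
                        paste(bad, collapse = ", "))
  defaults[names(intensity)] <- intensity
  structure(list(nCells = as.integer(nCells),
                 imageShape = as.integer(imageShape),
                 nucleusRadius = nucleusRadius, ringWidth = ringWidth,
                 assay = assay, responderFraction = responderFraction,
                 deadFraction = deadFraction,
                 granuleCount = as.integer(granuleCount),
                 granuleSigma = granuleSigma, granuleMass = granuleMass,
                 cellGap = cellGap,
                 nDebris = as.integer(nDebris), intensity = defaults,
                 readSd = readSd, seed = as.integer(seed)),
            class = "FieldSpec")
}

# rejection-sampled non-overlapping centres; max 1e4 attempts per cell
.placeNuclei <- function(n, h, w, radii, margin, gap = 6) {
  cx <- cy <- numeric(n)
  if (2 * margin >= h || 2 * margin >= w)
    stop("image too small to place nuclei: margin ", margin,
         " exceeds half the image extent")
  for (i in seq_len(n)) {
    placed <- FALSE
    for (att in seq_len(10000L)) {
      x <- stats::runif(1, margin, w - margin)
      y <- stats::runif(1, margin, h - margin)
      if (i == 1 || all((cx[seq_len(i - 1)] - x)^2 + (cy[seq_len(i - 1)] - y)^2 >
                        (radii[seq_len(i - 1)] + radii[i] + gap)^2)) {
        cx[i] <- x; cy[i] <- y; placed <- TRUE
        break
      }
    }
    if (!placed)
      stop("placement failure: could not place ", n,
           " non-overlapping nuclei in a ", h, " x ", w, " image")
  }
  cbind(y = cy, x = cx)
}

# add a filled (rotated) ellipse of label `lab` to an integer raster
.paintEllipse <- function(mask, cy, cx, a, b, theta) {
  h <- nrow(mask); w <- ncol(mask)
  r <- ceiling(max(a, b))
  ys <- max(1, floor(cy - r)):min(h, ceiling(cy + r))
  xs <- max(1, floor(cx - r)):min(w, ceiling(cx + r))
  dy <- outer(ys - cy, rep(1, length(xs)))
  dx <- outer(rep(1, length(ys)), xs - cx)
  u <- (dy * cos(theta) + dx * sin(theta)) / a
  v <- (-dy * sin(theta) + dx * cos(theta)) / b
  mask[ys, xs][u^2 + v^2 <= 1] <- TRUE
  mask
}

# add a Gaussian spot of integrated mass m and width sigma
.paintSpot <- function(img, cy, cx, m, sigma) {
  h <- nrow(img); w <- ncol(img)
  r <- ceiling(3 * sigma)
  ys <- max(1, cy - r):min(h, cy + r)
  xs <- max(1, cx - r):min(w, cx + r)
  dy2 <- outer((ys - cy)^2, rep(1, length(xs)))
  dx2 <- outer(rep(1, length(ys)), (xs - cx)^2)
  img[ys, xs] <- img[ys, xs] +
    m / (2 * pi * sigma^2) * exp(-(dy2 + dx2) / (2 * sigma^2))
  img
}

#' Generate one synthetic microscopy view field with ground truth
#'
#' Renders a view field according to a \code{\link{fieldSpec}}: ellipsoidal
#' non-overlapping nuclei in the Hoechst channel, a GFP biosensor channel
#' whose rendering depends on the assay (diffuse versus granular cytoplasm
#' for CALR-GFP and quinacrine, nuclear retention versus release for
#' HMGB1-GFP, whole-cell induction for the MX1 reporter), and a PI channel
#' marking dead cells (which also appear condensed and brighter in the
#' Hoechst channel). Expected counts receive Poisson shot noise plus
#' additive Gaussian read noise, emulating an sCMOS camera.
#'
#' Granule-bearing cells (responders for CALR-GFP, non-responders for
#' quinacrine, whose vesicles are depleted on treatment) redistribute a
#' fixed per-granule intensity mass from the diffuse cytoplasmic pool into
#' Gaussian puncta, so total cell intensity is approximately conserved
#' across granule counts.
#'
#' @param spec a \code{\link{fieldSpec}}
#' @param well,field metadata stamped on the returned
#'   \linkS4class{FieldImage}
#' @return list with elements \code{field} (a \linkS4class{FieldImage} with
#'   channels Hoechst, GFP, PI) and \code{truth} (data.frame with one row
#'   per cell: \code{cell_id}, \code{y}, \code{x}, \code{radius},
#'   \code{dead}, \code{responder}, \code{granule_count},
#'   \code{expression}; attribute \code{granuleCenters} holds planted spot
#'   centres, attribute \code{nDebris} the planted speck count)
#' @examples
#' ft <- generateField(fieldSpec(nCells = 20, responderFraction = 0.5,
#'                               seed = 42))
#' ft$field
#' table(ft$truth$responder)
#' @export
generateField <- function(spec, well = "A01", field = 1L) {
  stopifnot(inherits(spec, "FieldSpec"))
  withr::with_seed(spec$seed, .renderField(spec, well, field))
}

.renderField <- function(spec, well, field) {
  h <- spec$imageShape[1]; w <- spec$imageShape[2]
  n <- spec$nCells
  ip <- spec$intensity
  emptyTruth <- data.frame(cell_id = integer(0), y = numeric(0),
                           x = numeric(0), radius = numeric(0),
                           dead = logical(0), responder = logical(0),
                           granule_count = integer(0),
                           expression = numeric(0))

  hoechst <- matrix(ip$background, h, w)
  gfp <- matrix(ip$background, h, w)
  pi_ch <- matrix(ip$background, h, w)

  if (n > 0) {
    radii <- pmax(2, stats::rnorm(n, spec$nucleusRadius[1], spec$nucleusRadius[2]))
    dead <- stats::runif(n) < spec$deadFraction
    responder <- stats::runif(n) < spec$responderFraction
    fac <- exp(stats::rnorm(n, 0, ip$cellCV))
    margin <- ceiling(max(radii) * 1.1 + spec$ringWidth + 2)
    ctr <- .placeNuclei(n, h, w, radii, margin, spec$cellGap)
    axA <- radii * stats::runif(n, 0.9, 1.1)
    axB <- radii * stats::runif(n, 0.9, 1.1)
    theta <- stats::runif(n, 0, pi)
    shrink <- ifelse(dead, ip$deadShrinkFactor, 1)

    nucLab <- matrix(0L, h, w)
    for (i in seq_len(n)) {
      m <- .paintEllipse(matrix(FALSE, h, w), ctr[i, 1], ctr[i, 2],
                         axA[i] * shrink[i], axB[i] * shrink[i], theta[i])
      nucLab[m] <- i
    }

    # cytoplasm: disc of radius r+ring around each centre, minus all
    # nuclei; contested pixels go to the nearest centre
    bestD <- matrix(Inf, h, w)
    cytoLab <- matrix(0L, h, w)
    for (i in seq_len(n)) {
      rc <- max(axA[i], axB[i]) * shrink[i] + spec$ringWidth
      ys <- max(1, floor(ctr[i, 1] - rc)):min(h, ceiling(ctr[i, 1] + rc))
      xs <- max(1, floor(ctr[i, 2] - rc)):min(w, ceiling(ctr[i, 2] + rc))
      d2 <- outer((ys - ctr[i, 1])^2, rep(1, length(xs))) +
            outer(rep(1, length(ys)), (xs - ctr[i, 2])^2)
      sel <- d2 <= rc^2 & d2 < bestD[ys, xs]
      bd <- bestD[ys, xs]; cl <- cytoLab[ys, xs]
      bd[sel] <- d2[sel]; cl[sel] <- i
      bestD[ys, xs] <- bd; cytoLab[ys, xs] <- cl
    }
    cytoLab[nucLab > 0] <- 0L

    # Hoechst and PI
    for (i in seq_len(n)) {
      m <- nucLab == i
      hoechst[m] <- hoechst[m] +
        ip$nucleusLevel * fac[i] * if (dead[i]) ip$deadHoechstFactor else 1
      if (dead[i]) pi_ch[m] <- pi_ch[m] + ip$piDeadLevel * fac[i]
    }

    # biosensor channel
    granular <- if (spec$assay == "CALR_GFP") responder
                else if (spec$assay == "QUINACRINE") !responder
                else rep(FALSE, n)
    nGran <- ifelse(granular, spec$granuleCount, 0L)
    granCenters <- NULL
    if (spec$assay %in% c("CALR_GFP", "QUINACRINE")) {
      for (i in seq_len(n)) {
        nm <- nucLab == i
        gfp[nm] <- gfp[nm] + ip$nucleusGfpLevel * fac[i]
        cm <- which(cytoLab == i)
        if (length(cm) == 0) next
        total <- ip$cytoplasmLevel * length(cm) * fac[i]
        gTot <- min(nGran[i] * spec$granuleMass * fac[i], 0.85 * total)
        gfp[cm] <- gfp[cm] + (total - gTot) / length(cm)
        if (nGran[i] > 0) {
          # keep puncta interior to the cell so their Gaussian tails stay
          # out of neighbouring cytoplasm regions
          cyy <- ((cm - 1) %% h) + 1
          cxx <- ((cm - 1) %/% h) + 1
          rmax <- max(axA[i], axB[i]) * shrink[i] + spec$ringWidth
          inner <- (cyy - ctr[i, 1])^2 + (cxx - ctr[i, 2])^2 <=
            (rmax - 2 * spec$granuleSigma)^2
          pool <- if (any(inner)) cm[inner] else cm
          pick <- pool[sample.int(length(pool), nGran[i], replace = TRUE)]
          gy <- ((pick - 1) %% h) + 1
          gx <- ((pick - 1) %/% h) + 1
          for (g in seq_len(nGran[i]))
            gfp <- .paintSpot(gfp, gy[g], gx[g], gTot / nGran[i],
                              spec$granuleSigma)
          granCenters <- rbind(granCenters,
                               data.frame(cell_id = i, y = gy, x = gx))
        }
      }
    } else if (spec$assay == "HMGB1_GFP") {
      for (i in seq_len(n)) {
        nm <- nucLab == i
        lvl <- ip$nuclearBiosensorLevel * fac[i] *
          if (responder[i]) ip$hmgb1ReleasedFactor else 1
        gfp[nm] <- gfp[nm] + lvl
        cm <- cytoLab == i
        gfp[cm] <- gfp[cm] + ip$nucleusGfpLevel * fac[i]
      }
    } else { # MX1_GFP: whole-cell reporter
      for (i in seq_len(n)) {
        m <- nucLab == i | cytoLab == i
        gfp[m] <- gfp[m] +
          fac[i] * if (responder[i]) ip$mx1Induced else ip$mx1Baseline
      }
    }
    truth <- data.frame(cell_id = seq_len(n), y = ctr[, 1], x = ctr[, 2],
                        radius = (axA + axB) / 2 * shrink, dead = dead,
                        responder = responder,
                        granule_count = as.integer(nGran),
                        expression = fac)
    attr(truth, "granuleCenters") <- granCenters
  } else {
    truth <- emptyTruth
    nucLab <- matrix(0L, h, w)
    radii <- numeric(0); ctr <- cbind(y = numeric(0), x = numeric(0))
  }

  # debris specks: small bright dots in the Hoechst channel, kept clear of
  # nuclei so they form separate objects
  if (spec$nDebris > 0) {
    placedDebris <- 0L
    for (att in seq_len(10000L)) {
      if (placedDebris >= spec$nDebris) break
      y <- stats::runif(1, 4, h - 4); x <- stats::runif(1, 4, w - 4)
      if (spec$nCells == 0 ||
          all((ctr[, 1] - y)^2 + (ctr[, 2] - x)^2 >
              (radii + spec$ringWidth + 4)^2)) {
        m <- .paintEllipse(matrix(FALSE, h, w), y, x, 1.4, 1.4, 0)
        hoechst[m] <- hoechst[m] + spec$intensity$debrisLevel
        placedDebris <- placedDebris + 1L
      }
    }
    attr(truth, "nDebris") <- placedDebris
  } else attr(truth, "nDebris") <- 0L

  noisy <- function(x) {
    v <- stats::rpois(length(x), x) + stats::rnorm(length(x), 0, spec$readSd)
    matrix(pmin(pmax(v, 0), 65535), nrow(x), ncol(x))
  }
  fieldImg <- new("FieldImage",
                  channels = list(Hoechst = noisy(hoechst),
                                  GFP = noisy(gfp), PI = noisy(pi_ch)),
                  well = well, field = as.integer(field))
  list(field = fieldImg, truth = truth)
}
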