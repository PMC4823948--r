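#' Gate viable (PI-negative) events
#'
#' Restricts an event table to living cells: events whose PI intensity
#' lies below the threshold. All downstream marker analysis is limited to
#' this viable gate.
#'
#' @param events data.frame with a \code{PI} column (and typically
#'   \code{event_id} and \code{marker})
#' @param piThreshold PI intensity threshold (> 0); see
#'   \code{\link{estimatePIThreshold}} for automatic calibration
#' @return list with \code{events} (the PI-negative subset) and
#'   \code{liveFraction} (retained fraction)
#' @examples
#' ev <- data.frame(event_id = 1:3, PI = c(0.1, 0.2, 5), marker = 1:3)
#' gateLive(ev, 1)$liveFraction  # 2/3
#' @export
gateLive <- function(events, piThreshold) {
  if (!"PI" %in% names(events)) stop("no PI column in event table")
  if (length(piThreshold) != 1 || piThreshold <= 0)
    stop("piThreshold must be a single value > 0")
  if (anyNA(events$PI)) stop("missing values in PI column")
  keep <- events$PI < piThreshold
  list(events = events[keep, , drop = FALSE],
       liveFraction = if (nrow(events)) mean(keep) else NA_real_)
}

#' Fraction of marker-positive events among viable cells
#'
#' Applies a calibrated threshold model to the marker intensities of a
#' live-gated event table and reports the positive fraction with an exact
#' (Clopper--Pearson) 95\% binomial confidence interval, together with
#' the mean marker intensity. An empty table yields an undefined result
#' flagged \code{"insufficient viable cells"}.
#'
#' @param liveEvents live-gated event table with a \code{marker} column
#' @param model a \linkS4class{ThresholdModel} calibrated on control
#'   samples (e.g. unstained versus positive control)
#' @return list with \code{fraction}, \code{ci} (length-2 vector),
#'   \code{n}, \code{positive} (count), \code{meanMarker}, \code{flag}
#' @export
markerPositiveFraction <- function(liveEvents, model) {
  stopifnot(is(model, "ThresholdModel"))
  n <- nrow(liveEvents)
  if (n == 0)
    return(list(fraction = NA_real_, ci = c(NA_real_, NA_real_), n = 0L,
                positive = NA_integer_, meanMarker = NA_real_,
                flag = "insufficient viable cells"))
  if (!"marker" %in% names(liveEvents)) stop("no marker column")
  pos <- sum(classifyPositive(liveEvents$marker, model))
  ci <- stats::binom.test(pos, n)$conf.int
  list(fraction = pos / n, ci = as.numeric(ci), n = n,
       positive = as.integer(pos), meanMarker = mean(liveEvents$marker),
       flag = NA_character_)
}

#' Estimate the PI viability threshold from unlabelled events
#'
#' Fits a two-component Gaussian mixture to log-transformed PI
#' intensities (cytometry intensities are approximately log-normal) and
#' places the threshold at the equal-likelihood intersection of the two
#' components, back-transformed to intensity units -- the same
#' control-Gaussian intersection rule used for the imaging assays,
#' applied unsupervised.
#'
#' @param events event table with a \code{PI} column
#' @return PI intensity threshold separating live (low) from dead (high)
#' @export
estimatePIThreshold <- function(events) {
  if (!"PI" %in% names(events)) stop("no PI column in event table")
  x <- log(events$PI + 1)
  # Mclust resolves its helpers in the calling frame
  mclustBIC <- mclust::mclustBIC
  fit <- mclust::Mclust(x, G = 2, modelNames = "V", verbose = FALSE)
  mu <- fit$parameters$mean
  sd <- sqrt(fit$parameters$variance$sigmasq)
  if (length(sd) == 1) sd <- rep(sd, 2)
  lo <- which.min(mu); hi <- which.max(mu)
  exp(.gaussianIntersection(mu[lo], sd[lo], mu[hi], sd[hi])) - 1
}
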