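#' Specification of a synthetic cytometry event table
#'
#' Parameters of the flow-cytometry-like event generator: a two-component
#' log-normal mixture for PI intensity (live events low, dead events high)
#' and, among live events, a two-component log-normal mixture for the
#' surface-marker intensity (CALR-AF488: negative versus positive).
#'
#' @param nEvents number of events (>= 0)
#' @param liveFraction fraction of events drawn from the live PI component
#' @param positiveFraction fraction of live events drawn from the
#'   marker-positive component
#' @param piLive,piDead \code{c(meanlog, sdlog)} of the live/dead PI
#'   log-normal components
#' @param markerNeg,markerPos \code{c(meanlog, sdlog)} of the
#'   marker-negative/-positive log-normal components
#' @param seed integer seed fixing the table exactly
#' @return an object of class \code{EventSpec}
#' @export
eventSpec <- function(nEvents = 10000L, liveFraction = 0.7,
                      positiveFraction = 0.3,
                      piLive = c(log(50), 0.35), piDead = c(log(2000), 0.35),
                      markerNeg = c(log(100), 0.4),
                      markerPos = c(log(1000), 0.4), seed = 1L) {
  if (nEvents < 0) stop("nEvents must be >= 0")
  if (liveFraction < 0 || liveFraction > 1)
    stop("liveFraction must lie in [0, 1]")
  if (positiveFraction < 0 || positiveFraction > 1)
    stop("positiveFraction must lie in [0, 1]")
  structure(list(nEvents = as.integer(nEvents), liveFraction = liveFraction,
                 positiveFraction = positiveFraction, piLive = piLive,
                 piDead = piDead, markerNeg = markerNeg,
                 markerPos = markerPos, seed = as.integer(seed)),
            class = "EventSpec")
}

#' Generate a synthetic cytometry event table
#'
#' Draws \code{nEvents} events from the mixtures of an
#' \code{\link{eventSpec}}. Dead events receive marker intensities from
#' the negative component (surface staining of permeabilised cells is not
#' modelled). Ground-truth component memberships are recorded in
#' \code{true_live} and \code{true_positive} columns, which the gating
#' functions ignore.
#'
#' @param spec an \code{\link{eventSpec}}
#' @return data.frame with columns \code{event_id}, \code{PI},
#'   \code{marker}, \code{true_live}, \code{true_positive}
#' @examples
#' ev <- generateEvents(eventSpec(nEvents = 1000, liveFraction = 0.8,
#'                                seed = 7))
#' mean(ev$true_live)
#' @export
generateEvents <- function(spec) {
  stopifnot(inherits(spec, "EventSpec"))
  withr::with_seed(spec$seed, {
    n <- spec$nEvents
    live <- stats::runif(n) < spec$liveFraction
    pos <- live & (stats::runif(n) < spec$positiveFraction)
    pi_int <- ifelse(live,
      stats::rlnorm(n, spec$piLive[1], spec$piLive[2]),
      stats::rlnorm(n, spec$piDead[1], spec$piDead[2]))
    marker <- ifelse(pos,
      stats::rlnorm(n, spec$markerPos[1], spec$markerPos[2]),
      stats::rlnorm(n, spec$markerNeg[1], spec$markerNeg[2]))
    data.frame(event_id = seq_len(n), PI = pi_int, marker = marker,
               true_live = live, true_positive = pos)
  })
}
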