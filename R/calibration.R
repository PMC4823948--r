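#' Calibrate a decision threshold from control distributions
#'
#' Fits a Gaussian (mean, SD) to the feature values of the negative and
#' positive control populations and places the decision threshold either
#' at the equal-likelihood intersection of the two fitted Gaussians
#' (\code{method = "intersection"}, the default) or at
#' \code{negMean + k * negSd} oriented by the positivity direction
#' (\code{method = "k_sigma"}). When no positive control values are
#' supplied, the method falls back to \code{k_sigma} with a warning.
#'
#' For equal SDs the intersection is the midpoint of the two means; for
#' unequal SDs it is the root of the quadratic equating the two Gaussian
#' log-densities that lies between the means.
#'
#' @param negValues,posValues feature values of the negative/positive
#'   control populations (>= 20 values each where supplied)
#' @param direction \code{"above"} if values above the threshold are
#'   positive, \code{"below"} otherwise
#' @param method \code{"intersection"} or \code{"k_sigma"}
#' @param k SD multiplier for \code{k_sigma}
#' @param assay assay label stored in the model
#' @return a \linkS4class{ThresholdModel}
#' @examples
#' fitThreshold(rnorm(100, 100, 10), rnorm(100, 200, 10))
#' @export
fitThreshold <- function(negValues, posValues = NULL,
                         direction = c("above", "below"),
                         method = c("intersection", "k_sigma"), k = 3,
                         assay = "") {
  direction <- match.arg(direction)
  method <- match.arg(method)
  negValues <- negValues[is.finite(negValues)]
  if (length(negValues) < 20)
    stop("at least 20 negative-control values are required")
  if (is.null(posValues) && method == "intersection") {
    warning("no positive-control values: falling back to k_sigma")
    method <- "k_sigma"
  }
  nm <- mean(negValues); ns <- stats::sd(negValues)
  if (ns == 0) stop("degenerate negative control (SD = 0)")
  pm <- ps <- NA_real_
  if (!is.null(posValues)) {
    posValues <- posValues[is.finite(posValues)]
    if (length(posValues) < 20)
      stop("at least 20 positive-control values are required")
    pm <- mean(posValues); ps <- stats::sd(posValues)
    if (ps == 0) stop("degenerate positive control (SD = 0)")
    if (pm == nm) stop("control means are equal: no separation to threshold")
  }
  thr <- if (method == "intersection") {
    .gaussianIntersection(nm, ns, pm, ps)
  } else {
    if (direction == "above") nm + k * ns else nm - k * ns
  }
  new("ThresholdModel", assay = assay, direction = direction,
      negMean = nm, negSd = ns, posMean = pm, posSd = ps,
      threshold = thr, k = k, method = method)
}

# equal-likelihood crossing of N(m1,s1) and N(m2,s2) between the means
.gaussianIntersection <- function(m1, s1, m2, s2) {
  if (isTRUE(all.equal(s1, s2))) return((m1 + m2) / 2)
  a <- 1 / (2 * s2^2) - 1 / (2 * s1^2)
  b <- m1 / s1^2 - m2 / s2^2
  cc <- m2^2 / (2 * s2^2) - m1^2 / (2 * s1^2) + log(s2 / s1)
  disc <- b^2 - 4 * a * cc
  if (disc < 0) stop("Gaussian intersection has no real root")
  roots <- (-b + c(-1, 1) * sqrt(disc)) / (2 * a)
  lo <- min(m1, m2); hi <- max(m1, m2)
  inside <- roots[roots >= lo & roots <= hi]
  if (length(inside) == 0)
    stop("no Gaussian intersection between the control means")
  inside[1]
}

#' Classify values as positive under a threshold model
#'
#' @param values feature values
#' @param model a \linkS4class{ThresholdModel}
#' @return logical vector (NA propagates)
#' @export
classifyPositive <- function(values, model) {
  stopifnot(is(model, "ThresholdModel"))
  if (model@direction == "above") values > model@threshold
  else values < model@threshold
}

#' Summarize per-cell records of one well
#'
#' Pools the per-cell records of all view fields of a single well and
#' computes the cell count, the number of viable (PI-low) cells and the
#' fraction of viable, QC-passing cells positive under the threshold
#' model. Wells with fewer than \code{minLive} viable cells are flagged
#' \code{"insufficient viable cells"} and carry an undefined fraction:
#' when too few cells exclude the dye, positivity among them cannot be
#' appreciated.
#'
#' @param records data.frame of \code{\link{measureField}} rows, all from
#'   one well
#' @param model a \linkS4class{ThresholdModel}
#' @param minLive minimum number of viable cells for a usable well
#' @return one-row data.frame: \code{well}, \code{n_cells}, \code{n_live},
#'   \code{fraction_positive}, \code{mean_feature} (mean over live
#'   QC-passing cells), \code{excluded}, \code{flag}
#' @export
summarizeWell <- function(records, model, minLive = 50) {
  stopifnot(is(model, "ThresholdModel"))
  wells <- unique(records$well)
  if (length(wells) > 1)
    stop("records from multiple wells: ", paste(wells, collapse = ", "))
  well <- if (length(wells)) wells else NA_character_
  nCells <- nrow(records)
  liveOk <- records$live & records$qc_ok
  nLive <- sum(records$live, na.rm = TRUE)
  if (nLive < minLive) {
    return(data.frame(well = well, n_cells = nCells, n_live = nLive,
                      fraction_positive = NA_real_, mean_feature = NA_real_,
                      excluded = TRUE, flag = "insufficient viable cells"))
  }
  vals <- records$feature[liveOk]
  vals <- vals[is.finite(vals)]
  data.frame(well = well, n_cells = nCells, n_live = nLive,
             fraction_positive = mean(classifyPositive(vals, model)),
             mean_feature = mean(vals), excluded = FALSE, flag = "")
}

#' Welch-corrected two-sample t-test
#'
#' Two-tailed Student's t-test with Welch correction (unequal variances,
#' Satterthwaite degrees of freedom), the group comparison used for all
#' well-level statistics. When both groups have zero variance and equal
#' means the test is degenerate and returns \code{t = 0, p = 1} by
#' convention.
#'
#' @param a,b numeric vectors (>= 2 values each)
#' @return list with \code{t}, \code{df}, \code{p}
#' @examples
#' welchTTest(c(1, 2, 3), c(4, 5, 6))  # t = -3.674, df = 4, p = 0.0213
#' @export
welchTTest <- function(a, b) {
  if (length(a) < 2 || length(b) < 2)
    stop("at least 2 values per group are required")
  if (stats::sd(a) == 0 && stats::sd(b) == 0) {
    if (mean(a) == mean(b))
      return(list(t = 0, df = length(a) + length(b) - 2, p = 1))
    return(list(t = sign(mean(a) - mean(b)) * Inf,
                df = length(a) + length(b) - 2, p = 0))
  }
  ht <- stats::t.test(a, b, var.equal = FALSE)
  list(t = unname(ht$statistic), df = unname(ht$parameter),
       p = ht$p.value)
}

#' Per-condition dose--response table with significance stars
#'
#' Aggregates well summaries by condition (treatment x dose), reporting
#' the mean and SD of the response across replicate wells and a
#' Welch-corrected two-tailed p-value against the untreated reference
#' wells, coded as \code{*} (p < 0.05), \code{**} (p < 0.01),
#' \code{***} (p < 0.001). No multiple-testing correction is applied
#' across doses (stars are per-comparison); set \code{holm = TRUE} to
#' Holm-adjust the p-values.
#'
#' @param summaries data.frame of well summaries (one row per well) with
#'   columns \code{treatment}, \code{dose}, \code{excluded} and the
#'   response column
#' @param reference data.frame of reference (untreated control) well
#'   summaries with the same response column
#' @param response name of the response column
#' @param holm apply a Holm correction across conditions
#' @return data.frame with one row per condition: \code{treatment},
#'   \code{dose}, \code{n_wells}, \code{mean}, \code{sd}, \code{t},
#'   \code{df}, \code{p}, \code{stars}
#' @export
doseResponseTable <- function(summaries, reference,
                              response = "fraction_positive",
                              holm = FALSE) {
  if (missing(reference) || is.null(reference) || nrow(reference) == 0)
    stop("missing reference (untreated control) wells")
  if (!response %in% names(summaries))
    stop("no response column '", response, "'")
  if ("excluded" %in% names(summaries))
    summaries <- summaries[!summaries$excluded, , drop = FALSE]
  if ("excluded" %in% names(reference))
    reference <- reference[!reference$excluded, , drop = FALSE]
  refVals <- reference[[response]]
  if (length(refVals) < 2)
    stop("at least 2 usable reference wells are required")
  key <- interaction(summaries$treatment, summaries$dose, drop = TRUE)
  grp <- split(summaries, key)
  rows <- lapply(grp, function(g) {
    vals <- g[[response]]
    tt <- if (length(vals) >= 2) welchTTest(vals, refVals)
          else list(t = NA_real_, df = NA_real_, p = NA_real_)
    data.frame(treatment = g$treatment[1], dose = g$dose[1],
               n_wells = length(vals), mean = mean(vals),
               sd = stats::sd(vals), t = tt$t, df = tt$df, p = tt$p)
  })
  out <- do.call(rbind, rows)
  out <- out[order(out$treatment, out$dose), , drop = FALSE]
  rownames(out) <- NULL
  if (holm) out$p <- stats::p.adjust(out$p, method = "holm")
  out$stars <- .stars(out$p)
  out
}
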