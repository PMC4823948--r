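#' Four-parameter logistic dose--response curve
#'
#' Evaluates the responder fraction at a given dose:
#' \deqn{f(d) = floor + (ceiling - floor)\, d^h / (d^h + EC_{50}^h)}
#' with \code{f(0) = floor}.
#'
#' @param dose numeric dose(s), same units as \code{ec50}
#' @param floor,ceiling lower and upper asymptotes in [0, 1]
#' @param ec50 half-maximal dose
#' @param hill Hill slope
#' @return responder fraction(s) in [floor, ceiling]
#' @export
logisticResponse <- function(dose, floor = 0.02, ceiling = 0.95,
                             ec50 = 100, hill = 2) {
  stopifnot(floor >= 0, ceiling <= 1, floor <= ceiling, ec50 > 0)
  ifelse(dose <= 0, floor,
         floor + (ceiling - floor) * dose^hill / (dose^hill + ec50^hill))
}

#' Default 24-well plate layout
#'
#' Three negative-control wells, three positive-control wells and six
#' doses in triplicate (18 treated wells), mirroring a control-anchored
#' dose--response plate design.
#'
#' @param doses the six treated doses
#' @return data.frame with columns \code{well}, \code{role}
#'   (\code{"neg"}, \code{"pos"} or \code{"treated"}), \code{treatment},
#'   \code{dose}
#' @export
defaultPlateLayout <- function(doses = c(12.5, 25, 50, 100, 200, 400)) {
  stopifnot(length(doses) == 6)
  wells <- paste0(rep(LETTERS[1:4], each = 6),
                  sprintf("%02d", rep(1:6, 4)))
  data.frame(
    well = wells,
    role = c(rep("neg", 3), rep("pos", 3), rep("treated", 18)),
    treatment = c(rep("untreated", 3), rep("positive_control", 3),
                  rep("drug", 18)),
    dose = c(rep(0, 6), rep(doses, each = 3)))
}

#' Simulate a full plate of view fields with ground truth
#'
#' For every well of a plate layout, generates \code{fieldsPerWell} view
#' fields (six by default, matching the acquisition design of six view
#' fields per well) whose true responder fraction is set by the well role:
#' 0 for negative controls, 1 for positive controls, and the logistic
#' dose--response evaluated at the well's dose for treated wells.
#'
#' @param layout plate layout data.frame with columns \code{well},
#'   \code{role} (\code{neg}/\code{pos}/\code{treated}), \code{treatment},
#'   \code{dose}; see \code{\link{defaultPlateLayout}}
#' @param assay biosensor assay to emulate (see \code{\link{fieldSpec}})
#' @param doseResponse list of logistic parameters (\code{floor},
#'   \code{ceiling}, \code{ec50}, \code{hill}) passed to
#'   \code{\link{logisticResponse}}
#' @param fieldsPerWell view fields per well
#' @param spec template \code{\link{fieldSpec}} supplying geometry,
#'   intensity and noise parameters (its \code{responderFraction} and
#'   \code{seed} are overridden per field)
#' @param seed master seed; per-field seeds are drawn from it
#' @return list with \code{fields} (list of \linkS4class{FieldImage}),
#'   \code{truth} (per-cell ground-truth data.frame with \code{well} and
#'   \code{field} columns), and \code{layout} (the input layout with a
#'   \code{true_fraction} column appended)
#' @export
generatePlate <- function(layout = defaultPlateLayout(), assay = "CALR_GFP",
                          doseResponse = list(floor = 0.02, ceiling = 0.95,
                                              ec50 = 100, hill = 2),
                          fieldsPerWell = 6L,
                          spec = fieldSpec(assay = assay), seed = 1L) {
  .checkAssay(assay)
  stopifnot(all(c("well", "role", "dose") %in% names(layout)))
  bad <- setdiff(unique(layout$role), c("neg", "pos", "treated"))
  if (length(bad))
    stop("unknown well role(s): ", paste(bad, collapse = ", "))
  dr <- modifyList(list(floor = 0.02, ceiling = 0.95, ec50 = 100, hill = 2),
                   doseResponse)
  layout$true_fraction <- ifelse(layout$role == "neg", 0,
    ifelse(layout$role == "pos", 1,
      logisticResponse(layout$dose, dr$floor, dr$ceiling, dr$ec50, dr$hill)))

  nw <- nrow(layout)
  fieldSeeds <- withr::with_seed(seed,
    sample.int(2147483646L, nw * fieldsPerWell))
  fields <- vector("list", nw * fieldsPerWell)
  truths <- vector("list", nw * fieldsPerWell)
  k <- 0L
  for (i in seq_len(nw)) {
    for (f in seq_len(fieldsPerWell)) {
      k <- k + 1L
      sp <- spec
      sp$assay <- assay
      sp$responderFraction <- layout$true_fraction[i]
      sp$seed <- fieldSeeds[k]
      ft <- generateField(sp, well = layout$well[i], field = f)
      fields[[k]] <- ft$field
      tr <- ft$truth
      if (nrow(tr)) {
        tr$well <- layout$well[i]
        tr$field <- f
      } else {
        tr$well <- character(0); tr$field <- integer(0)
      }
      truths[[k]] <- tr
    }
  }
  list(fields = fields, truth = do.call(rbind, truths), layout = layout)
}
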