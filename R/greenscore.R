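# Green Score and its genetic-diversity-corrected variant over spatial
# units.

#' Spatial-unit state weights for the Green Score
#'
#' Two presets are shipped. `"iucn"` is the published weighting (absent 0,
#' present 3, viable 6, functional 9; functional-state weight W_F = 9).
#' `"box1"` (functional 12, viable 9, W_F = 12) is the weighting under
#' which the towhee worked examples reproduce exactly; its `present` weight
#' is kept at 3 (the lower states are not exercised by those examples).
#' See the methods vignette for the discrepancy discussion.
#'
#' @param preset `"box1"` (default) or `"iucn"`.
#' @return list of class `green_weights`: `states` (named numeric) and
#'   `w_f`.
#' @export
green_weights <- function(preset = c("box1", "iucn")) {
  preset <- match.arg(preset)
  w <- switch(preset,
    box1 = list(states = c(absent = 0, present = 3, viable = 9,
                           functional = 12), w_f = 12),
    iucn = list(states = c(absent = 0, present = 3, viable = 6,
                           functional = 9), w_f = 9))
  structure(c(w, list(preset = preset)), class = "green_weights")
}

.unit_weights <- function(units, weights) {
  if (!nrow(units)) stop("at least one spatial unit is required")
  bad <- setdiff(units$state, names(weights$states))
  if (length(bad)) stop("unknown spatial-unit state(s): ",
                        paste(unique(bad), collapse = ", "))
  unname(weights$states[units$state])
}

#' Green Score
#'
#' `G = sum_S W_S / (W_F x N) x 100`: the recovery score over `N` spatial
#' units, each weighted by its state, relative to every unit being in the
#' functional state.
#'
#' @param units data frame with columns `state` (one of `absent`,
#'   `present`, `viable`, `functional`) and optionally `label`, `gd`.
#' @param weights a [green_weights()] preset.
#' @return list of class `green_result`: `score` (0-100), `corrected`
#'   (`FALSE`), `n_units`, `preset`.
#' @examples
#' green_score(data.frame(state = rep("functional", 9)))$score  # 100
#' @export
green_score <- function(units, weights = green_weights("box1")) {
  ws <- .unit_weights(units, weights)
  score <- sum(ws) / (weights$w_f * nrow(units)) * 100
  structure(list(score = score, corrected = FALSE, n_units = nrow(units),
                 preset = weights$preset, gd_lc = NULL),
            class = "green_result")
}

#' Genetic-diversity-corrected Green Score
#'
#' Each unit's weight is discounted by its relative genetic diversity,
#' `min(GD_S / GD_LC, 1)`, where `GD_S` is the unit's diversity (e.g. its
#' heterozygosity) and `GD_LC` the average diversity of related
#' Least-Concern species: `G = sum_S W_S (GD_S / GD_LC) / (W_F x N) x 100`.
#' The cap at 1 means the correction can never raise a score.
#'
#' @param units data frame with columns `state` and `gd` (>= 0), and
#'   optionally `label`.
#' @param weights a [green_weights()] preset.
#' @param gd_lc reference diversity of Least-Concern relatives (> 0).
#' @return list of class `green_result` with `corrected = TRUE`.
#' @export
gd_corrected_green_score <- function(units,
                                     weights = green_weights("box1"),
                                     gd_lc) {
  stopifnot(is.numeric(gd_lc), gd_lc > 0)
  ws <- .unit_weights(units, weights)
  if (is.null(units$gd) || any(is.na(units$gd))) {
    lab <- if (!is.null(units$label)) {
      paste(units$label[is.null(units$gd) | is.na(units$gd)],
            collapse = ", ")
    } else "some units"
    stop("missing gd value for unit(s): ", lab)
  }
  rel <- pmin(units$gd / gd_lc, 1)
  score <- sum(ws * rel) / (weights$w_f * nrow(units)) * 100
  structure(list(score = score, corrected = TRUE, n_units = nrow(units),
                 preset = weights$preset, gd_lc = gd_lc),
            class = "green_result")
}

#' @export
print.green_result <- function(x, ...) {
  cat(sprintf("%sGreen Score: %.3f (%d unit%s, %s weights)\n",
              if (x$corrected) "GD-corrected " else "", x$score,
              x$n_units, if (x$n_units == 1) "" else "s", x$preset))
  invisible(x)
}

#' Reference diversity of Least-Concern relatives
#'
#' Arithmetic mean of the supplied diversity values (e.g. mean H of
#' Least-Concern species in the same group); a convenience for producing
#' the `gd_lc` scalar.
#'
#' @param gd_values numeric vector of diversity values (> 0).
#' @return their mean.
#' @export
gd_lc_reference <- function(gd_values) {
  stopifnot(length(gd_values) >= 1, all(gd_values > 0))
  mean(gd_values)
}
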