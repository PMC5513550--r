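#' Ecoclimatic Index
#'
#' The overall annual favourability, in `[0, 100]`: the annual growth
#' index discounted by the multiplicative stress survival factor, gated
#' by the generation-length requirement — if the annual degree-days
#' above `DV0` fall short of `PDD`, the location cannot complete a
#' generation and `EI = 0` regardless of growth.
#'
#' @param gi_a annual growth index in `[0, 100]`.
#' @param stresses a [stress_result()] object.
#' @param dd_annual annual degree-days above `DV0`.
#' @param p a [climex_params()] object.
#' @return EI in `[0, 100]` (real-valued; classification rounds).
#' @export
#' @examples
#' p <- preset_params("current")
#' ecoclimatic_index(60, stress_result(cold = 50), 400, p)  # 30
ecoclimatic_index <- function(gi_a, stresses, dd_annual, p) {
  stopifnot(gi_a >= 0, gi_a <= 100, dd_annual >= 0,
            inherits(stresses, "stress_result"))
  if (dd_annual < p$PDD) return(0)
  gi_a * stresses$combined_factor
}

EI_CLASSES <- c("unsuitable", "marginal", "suitable", "highly_suitable",
                "optimal")

#' Suitability class of an Ecoclimatic Index value
#'
#' The conventional class scheme: unsuitable `EI = 0`; marginal `1-4`;
#' suitable `5-9`; highly suitable `10-29`; optimal `30-100`. Real-valued
#' EI is rounded half-up to the nearest integer before classification
#' (so EI below 0.5 is unsuitable).
#'
#' @param ei EI value(s) in `[0, 100]` (vectorised).
#' @return Factor with levels unsuitable, marginal, suitable,
#'   highly_suitable, optimal.
#' @export
classify_ei <- function(ei) {
  if (any(ei < 0 | ei > 100)) stop("EI must lie in [0,100]", call. = FALSE)
  r <- floor(ei + 0.5)   # round half-up to integer boundaries
  cls <- cut(r, breaks = c(-0.5, 0.5, 4.5, 9.5, 29.5, 100.5),
             labels = EI_CLASSES)
  factor(as.character(cls), levels = EI_CLASSES)
}

#' Is a location climatically suitable?
#'
#' Suitability means a rounded EI of at least 1 — the same threshold
#' used when matching modelled range to occurrence records.
#'
#' @param ei EI value(s) in `[0, 100]`.
#' @return Logical vector.
#' @export
is_suitable <- function(ei) {
  floor(ei + 0.5) >= 1
}
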