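#' Round half away from zero at a fixed number of decimals
#'
#' Commercial ("half-up") rounding used for all pence arithmetic, unlike
#' [base::round()]'s round-half-to-even. A tiny relative epsilon guards
#' against binary representation error (e.g. `2.675 * 100` being stored
#' just below `267.5`).
#'
#' @param x numeric vector.
#' @param digits decimal places to keep (default 2, i.e. pence).
#' @return numeric vector rounded half-up.
#' @examples
#' round_half_up(c(2.675, 362.0833, 0.005))
#' @export
round_half_up <- function(x, digits = 2) {
  p <- 10^digits
  xp <- x * p
  sign(xp) * floor(abs(xp) + 0.5 + pmax(abs(xp), 1) * 1e-9) / p
}

#' Integer pence representation of a GBP amount
#'
#' Converts pound amounts carrying at most two decimals to integer pence so
#' that conservation identities (total = linked + excluded) can be checked
#' exactly.
#'
#' @param x numeric vector of GBP amounts with at most 2 decimals.
#' @return integer vector of pence.
#' @export
as_pence <- function(x) as.integer(round(x * 100))

#' The nine English regions
#'
#' Region names used throughout the registry, enrichment and stratified
#' analyses.
#'
#' @return character vector of length 9.
#' @export
english_regions <- function() {
  c(
    "East Midlands", "East of England", "London", "North East England",
    "North West England", "South East England", "South West England",
    "West Midlands", "Yorkshire and the Humber"
  )
}

#' Payment categories
#'
#' The three transfer-of-value categories disclosed for healthcare
#' organisations: donations and grants, contributions to the costs of
#' events, and fees for service and consultancy.
#'
#' @return character vector of length 3.
#' @export
payment_categories <- function() {
  c("donation_grant", "event_contribution", "service_consultancy")
}

# type-7 sample quantile, the convention used for every quartile/IQR here
q7 <- function(x, p) unname(stats::quantile(x, p, type = 7, names = FALSE))
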