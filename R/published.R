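#' Published 2015 Disclosure UK summary figures for general practices
#'
#' Small reference tables shipped with the package, transcribed from the
#' published 2015 analysis of payments to English general practices:
#' `published_top10()` returns the top-10 donor table (per-company total
#' value, payment count, practices paid and single-payment quartiles);
#' `published_totals()` returns the headline accounting figures (total and
#' excluded payments, value and distinct recipient practices). They allow
#' the concentration and exclusion arithmetic to be exercised against the
#' published numbers without the original extract. One transcription note:
#' the published Napp median is typeset "38.49.00" and is stored as 38.49.
#'
#' @return `published_top10()`: a tibble with one row per donor.
#'   `published_totals()`: a named numeric vector.
#' @examples
#' sum(published_top10()$total_value_gbp)
#' published_totals()[["value_total_gbp"]]
#' @export
published_top10 <- function() {
  path <- system.file("extdata", "disclosure2015_top10.csv", package = "paynet")
  tibble::as_tibble(read.csv(path, check.names = FALSE))
}

#' @rdname published_top10
#' @export
published_totals <- function() {
  path <- system.file("extdata", "disclosure2015_totals.csv", package = "paynet")
  tab <- read.csv(path, check.names = FALSE)
  setNames(tab$value, tab$quantity)
}
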