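#' Quartile labels with type-7 cut points
#'
#' Cut points are the type-7 sample quantiles at 0.25/0.50/0.75 of the
#' supplied values; a value gets label `k` when it is at most the k-th cut
#' point (ties go to the lower quartile), label 4 otherwise. Label 1 always
#' holds the lowest values — for deprivation deciles that is the most
#' deprived quartile.
#'
#' @param values numeric vector (at least one value; four or more distinct
#'   values recommended for the labels to be meaningful).
#' @return integer labels in 1..4, same length as `values`.
#' @examples
#' assign_quartiles(1:8) # 1 1 2 2 3 3 4 4
#' assign_quartiles(1:5) # 1 1 2 3 4
#' @export
assign_quartiles <- function(values) {
  if (length(values) == 0 || all(is.na(values))) {
    abort("assign_quartiles() needs at least one value", class = "paynet_input_error")
  }
  cuts <- q7(values, c(0.25, 0.5, 0.75))
  lab <- 1L + (values > cuts[1]) + (values > cuts[2]) + (values > cuts[3])
  as.integer(lab)
}

#' Profile payment-receiving practices
#'
#' One row per practice that received at least one linked payment: its
#' registry characteristics (region, list size, share of patients over 65,
#' deprivation decile), payment aggregates (total value, payment count,
#' distinct donor count), and the three quartile groupings used in the
#' stratified comparisons. Quartiles are computed over the
#' payment-receiving practices (the analysis population), not the whole
#' registry.
#'
#' @param linked linked payments tibble (the `linked` element of
#'   [link_payments()]).
#' @param registry practice registry tibble.
#' @return tibble of practice profiles with columns `practice_code`,
#'   `region`, `n_registered`, `share_over_65`, `imd_decile`,
#'   `total_value_gbp`, `n_payments`, `n_companies`, `size_quartile`,
#'   `elderly_quartile`, `imd_quartile`.
#' @export
profile_practices <- function(linked, registry) {
  missing_codes <- setdiff(linked$practice_code, registry$practice_code)
  if (length(missing_codes) > 0) {
    abort(
      paste0(
        "linked practice code(s) absent from registry: ",
        paste(head(sort(missing_codes), 5), collapse = ", ")
      ),
      class = "paynet_input_error"
    )
  }
  agg <- linked |>
    dplyr::group_by(.data$practice_code) |>
    dplyr::summarise(
      total_value_gbp = sum(as_pence(.data$amount_gbp)) / 100,
      n_payments = dplyr::n(),
      n_companies = dplyr::n_distinct(.data$company),
      .groups = "drop"
    )
  out <- agg |>
    dplyr::left_join(
      registry[, c(
        "practice_code", "region", "n_registered", "n_over65", "imd_decile"
      )],
      by = "practice_code"
    ) |>
    dplyr::mutate(
      share_over_65 = .data$n_over65 / .data$n_registered,
      size_quartile = assign_quartiles(.data$n_registered),
      elderly_quartile = assign_quartiles(.data$share_over_65),
      imd_quartile = assign_quartiles(.data$imd_decile)
    ) |>
    dplyr::select(
      "practice_code", "region", "n_registered", "share_over_65",
      "imd_decile", "total_value_gbp", "n_payments", "n_companies",
      "size_quartile", "elderly_quartile", "imd_quartile"
    )
  out
}
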