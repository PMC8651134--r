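#' Five-number summary with type-7 quartiles
#'
#' @param values nonempty numeric vector.
#' @return one-row tibble: `n`, `min`, `q1`, `median`, `q3`, `max`.
#' @examples
#' payment_summary(1:5)
#' @export
payment_summary <- function(values) {
  if (length(values) == 0) {
    abort("payment_summary() needs at least one value", class = "paynet_input_error")
  }
  tibble::tibble(
    n = length(values),
    min = min(values),
    q1 = q7(values, 0.25),
    median = q7(values, 0.5),
    q3 = q7(values, 0.75),
    max = max(values)
  )
}

#' Distribution summary table of payments, values and counterparties
#'
#' The standard descriptive table of a payments year: distributions of
#' single-payment values, per-practice totals and counts, per-company
#' totals and counts, practices per company, and companies per practice.
#'
#' @param linked linked payments tibble.
#' @return tibble with a `level` column and the [payment_summary()] fields.
#' @export
summary_table <- function(linked) {
  per_practice <- linked |>
    dplyr::group_by(.data$practice_code) |>
    dplyr::summarise(
      value = sum(as_pence(.data$amount_gbp)) / 100,
      n = dplyr::n(),
      n_companies = dplyr::n_distinct(.data$company),
      .groups = "drop"
    )
  per_company <- linked |>
    dplyr::group_by(.data$company) |>
    dplyr::summarise(
      value = sum(as_pence(.data$amount_gbp)) / 100,
      n = dplyr::n(),
      n_practices = dplyr::n_distinct(.data$practice_code),
      .groups = "drop"
    )
  dplyr::bind_rows(
    single_payment_value = payment_summary(linked$amount_gbp),
    value_per_practice = payment_summary(per_practice$value),
    payments_per_practice = payment_summary(per_practice$n),
    value_per_company = payment_summary(per_company$value),
    payments_per_company = payment_summary(per_company$n),
    practices_per_company = payment_summary(per_company$n_practices),
    companies_per_practice = payment_summary(per_practice$n_companies),
    .id = "level"
  )
}

#' Concentration table by company or practice
#'
#' Per-entity totals, payment counts, distinct counterparties and
#' single-payment quartiles, ranked by descending total value with ties
#' broken by entity name for deterministic output.
#'
#' @param linked nonempty linked payments tibble.
#' @param axis `"company"` (entities are donors, counterparties are
#'   practices) or `"practice"`.
#' @return tibble: `entity`, `total_value_gbp`, `n_payments`,
#'   `n_counterparties`, `q1`, `median_single_payment`, `q3`, `rank`.
#' @export
concentration <- function(linked, axis = c("company", "practice")) {
  axis <- match.arg(axis)
  if (nrow(linked) == 0) abort("linked table is empty", class = "paynet_input_error")
  key <- if (axis == "company") "company" else "practice_code"
  other <- if (axis == "company") "practice_code" else "company"
  out <- linked |>
    dplyr::group_by(entity = .data[[key]]) |>
    dplyr::summarise(
      total_value_gbp = sum(as_pence(.data$amount_gbp)) / 100,
      n_payments = dplyr::n(),
      n_counterparties = dplyr::n_distinct(.data[[other]]),
      q1 = q7(.data$amount_gbp, 0.25),
      median_single_payment = q7(.data$amount_gbp, 0.5),
      q3 = q7(.data$amount_gbp, 0.75),
      .groups = "drop"
    ) |>
    dplyr::arrange(dplyr::desc(.data$total_value_gbp), .data$entity) |>
    dplyr::mutate(rank = dplyr::row_number())
  out
}

#' Share captured by the top k entities
#'
#' @param conc a [concentration()] table (or any tibble with `entity`,
#'   `total_value_gbp`, `n_payments` ranked columns).
#' @param k number of top entities, `1 <= k <= nrow(conc)`.
#' @param basis `"value"` (GBP totals) or `"count"` (payment counts).
#' @param denominator total to divide by; defaults to the column sum of
#'   `conc`, but can be supplied when the table covers only the top
#'   entities of a larger population.
#' @return fraction in `[0, 1]`.
#' @examples
#' tab <- tibble::tibble(
#'   entity = c("a", "b", "c"), total_value_gbp = c(10, 5, 5),
#'   n_payments = c(1, 1, 1)
#' )
#' top_k_share(tab, 1, denominator = 20) # 0.5
#' @export
top_k_share <- function(conc, k, basis = c("value", "count"), denominator = NULL) {
  basis <- match.arg(basis)
  if (k < 1 || k > nrow(conc)) {
    abort("k must lie between 1 and the number of entities",
      class = "paynet_input_error"
    )
  }
  col <- if (basis == "value") conc$total_value_gbp else conc$n_payments
  ord <- order(-col, conc$entity)
  denominator <- denominator %||% sum(col)
  if (denominator <= 0) abort("denominator must be positive", class = "paynet_input_error")
  sum(col[ord[seq_len(k)]]) / denominator
}

#' Category breakdown of payment value
#'
#' Value-weighted (default) or count-weighted shares of the three payment
#' categories; shares sum to 1.
#'
#' @param linked nonempty linked payments tibble; optionally pre-filtered
#'   to one company for a per-company breakdown.
#' @param weight `"value"` or `"count"`.
#' @return tibble `category`, `share`, covering all three categories (zero
#'   shares included).
#' @export
category_breakdown <- function(linked, weight = c("value", "count")) {
  weight <- match.arg(weight)
  if (nrow(linked) == 0) abort("linked table is empty", class = "paynet_input_error")
  w <- if (weight == "value") as_pence(linked$amount_gbp) else rep(1L, nrow(linked))
  tot <- tapply(w, factor(linked$category, levels = payment_categories()), sum)
  tot[is.na(tot)] <- 0
  tibble::tibble(
    category = payment_categories(),
    share = as.numeric(tot) / sum(tot)
  )
}
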