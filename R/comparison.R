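# exact null distribution of the Mann-Whitney U statistic: number of ways
# to choose m of m+n ranks giving each U value, by the standard counting
# recursion c(u; m, n) = c(u - n; m - 1, n) + c(u; m, n - 1)
u_null_counts <- function(m, n) {
  umax <- m * n
  # dimensions: u in 0..umax, i in 0..m, j in 0..n
  C <- array(0, dim = c(umax + 1, m + 1, n + 1))
  C[1, , ] <- 1 # u = 0 is always achievable (take the lowest ranks)
  for (i in 1:m) {
    for (j in 1:n) {
      for (u in 1:(i * j)) {
        from_i <- if (u - j >= 0) C[u - j + 1, i, j + 1] else 0
        C[u + 1, i + 1, j + 1] <- from_i + C[u + 1, i + 1, j]
      }
    }
  }
  C[, m + 1, n + 1]
}

#' Wilcoxon rank-sum (Mann-Whitney) test
#'
#' Two-sided rank-sum test of two independent samples. The statistic is
#' `U = R_x - n_x (n_x + 1) / 2` with midranks for ties. `exact` mode
#' evaluates the permutation null distribution exactly (valid only without
#' ties) and reports `p = min(1, 2 min(P(U <= u), P(U >= u)))`.
#' `normal_approx` uses the tie-corrected variance
#' `n_x n_y / 12 ((n + 1) - sum(t^3 - t) / (n (n - 1)))` with a 0.5
#' continuity correction. `auto` picks exact when `n_x + n_y <= 20` and
#' there are no ties, otherwise the normal approximation. p-values are
#' clipped to `[0, 1]`.
#'
#' @param x,y nonempty numeric samples.
#' @param mode `"auto"` (default), `"exact"` or `"normal_approx"`.
#' @return list with `statistic` (U for the `x` sample), `p_value`, and
#'   `mode` actually used.
#' @examples
#' rank_sum_test(c(1, 2), c(3, 4), mode = "exact")$p_value # 1/3
#' @export
rank_sum_test <- function(x, y, mode = c("auto", "exact", "normal_approx")) {
  mode <- match.arg(mode)
  if (length(x) == 0 || length(y) == 0) {
    abort("both samples must be nonempty", class = "paynet_input_error")
  }
  nx <- length(x)
  ny <- length(y)
  n <- nx + ny
  r <- rank(c(x, y))
  has_ties <- anyDuplicated(c(x, y)) > 0
  U <- sum(r[seq_len(nx)]) - nx * (nx + 1) / 2

  if (mode == "auto") {
    mode <- if (n <= 20 && !has_ties) "exact" else "normal_approx"
  }
  if (mode == "exact") {
    if (has_ties) {
      abort("exact mode is invalid with ties; use mode = \"normal_approx\"",
        class = "paynet_input_error"
      )
    }
    counts <- u_null_counts(nx, ny)
    total <- sum(counts)
    lower <- sum(counts[seq_len(U + 1)]) / total
    upper <- sum(counts[(U + 1):length(counts)]) / total
    p <- min(1, 2 * min(lower, upper))
  } else {
    tie_tab <- table(r)
    sig2 <- nx * ny / 12 * ((n + 1) - sum(tie_tab^3 - tie_tab) / (n * (n - 1)))
    if (sig2 <= 0) {
      p <- 1
    } else {
      z <- max(0, abs(U - nx * ny / 2) - 0.5) / sqrt(sig2)
      p <- min(1, 2 * pnorm(-z))
    }
  }
  list(statistic = U, p_value = p, mode = mode)
}

grouping_choices <- function() {
  c("region", "size_quartile", "elderly_quartile", "imd_quartile")
}

default_reference <- function(grouping) {
  if (grouping == "region") "London" else "1"
}

#' Stratified rank-sum comparison of payment values
#'
#' For one practice characteristic (region or a quartile grouping),
#' compares each stratum's payment values against a stated reference
#' stratum with the two-sided Wilcoxon rank-sum test. The unit of analysis
#' is the per-practice total payment value by default; a per-payment
#' variant is available. No multiplicity adjustment is applied — raw
#' p-values are reported per stratum.
#'
#' @param profiles practice profiles from [profile_practices()].
#' @param grouping one of `"region"`, `"size_quartile"`,
#'   `"elderly_quartile"`, `"imd_quartile"`.
#' @param reference reference stratum label; defaults to `"London"` for
#'   regions and quartile 1 otherwise.
#' @param alpha significance threshold (default 0.05).
#' @param unit `"practice"` (per-practice totals, default) or `"payment"`
#'   (individual payment values; requires `linked`).
#' @param linked linked payments tibble, needed when `unit = "payment"`.
#' @param mode test mode passed to [rank_sum_test()].
#' @return tibble: `grouping`, `stratum`, `n_practices`, `median`, `q1`,
#'   `q3`, `p_value` (`NA` for the reference), `significant`,
#'   `is_reference`. The reference row comes first.
#' @export
stratified_comparison <- function(profiles, grouping, reference = NULL,
                                  alpha = 0.05,
                                  unit = c("practice", "payment"),
                                  linked = NULL,
                                  mode = "auto") {
  unit <- match.arg(unit)
  if (!grouping %in% grouping_choices()) {
    abort(
      paste0(
        "unknown grouping; use one of: ",
        paste(grouping_choices(), collapse = ", ")
      ),
      class = "paynet_input_error"
    )
  }
  reference <- reference %||% default_reference(grouping)
  strata <- as.character(profiles[[grouping]])
  if (!reference %in% strata) {
    abort(paste0("reference stratum ", dQuote(reference), " is empty or absent"),
      class = "paynet_input_error"
    )
  }
  if (unit == "practice") {
    values <- profiles$total_value_gbp
    units_strata <- strata
    n_by_stratum <- table(strata)
  } else {
    if (is.null(linked)) {
      abort("unit = \"payment\" requires the linked payments table",
        class = "paynet_input_error"
      )
    }
    map <- setNames(strata, profiles$practice_code)
    values <- linked$amount_gbp
    units_strata <- as.character(map[linked$practice_code])
    n_by_stratum <- table(strata) # practice counts still reported
  }
  labels <- sort(unique(strata))
  labels <- c(reference, setdiff(labels, reference))
  ref_values <- values[units_strata == reference]
  rows <- lapply(labels, function(lab) {
    v <- values[units_strata == lab]
    is_ref <- identical(lab, reference)
    p <- if (is_ref) NA_real_ else rank_sum_test(v, ref_values, mode = mode)$p_value
    tibble::tibble(
      grouping = grouping,
      stratum = lab,
      n_practices = as.integer(n_by_stratum[[lab]]),
      median = q7(v, 0.5),
      q1 = q7(v, 0.25),
      q3 = q7(v, 0.75),
      p_value = p,
      significant = if (is_ref) NA else p < alpha,
      is_reference = is_ref
    )
  })
  dplyr::bind_rows(rows)
}
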