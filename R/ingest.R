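payments_schema <- c(
  "company", "institution_name", "institution_location",
  "category", "amount_gbp", "vat_basis"
)
registry_schema <- c(
  "practice_code", "name", "address", "postcode", "region",
  "n_registered", "n_over65", "imd_decile"
)

# validate one character column of amounts: digits with an optional
# 1-2 decimal fraction, strictly positive
amount_ok <- function(x) grepl("^[0-9]+(\\.[0-9]{1,2})?$", x) & suppressWarnings(as.numeric(x)) > 0

#' Read and validate a payments table
#'
#' Reads a comma-separated payments file with header columns `company`,
#' `institution_name`, `institution_location`, `category`, `amount_gbp`,
#' `vat_basis`. Unknown extra columns are dropped with a warning (tolerant
#' reader); a missing required column is a schema error. Row-level problems
#' (non-numeric or non-positive amounts, unknown categories) are collected
#' and reported together with their data row numbers rather than silently
#' dropped. Blank or missing `vat_basis` becomes `"unknown"`.
#'
#' @param path path to the CSV file.
#' @return tibble of validated payments with a leading `payment_id` column
#'   (the data row number).
#' @export
read_payments <- function(path) {
  if (!file.exists(path)) abort(paste0("no such file: ", path))
  raw <- read.csv(path, colClasses = "character", check.names = FALSE)
  missing_cols <- setdiff(payments_schema, names(raw))
  if (length(missing_cols) > 0) {
    abort(
      paste0("payments file lacks required column(s): ",
        paste(missing_cols, collapse = ", ")
      ),
      class = "paynet_schema_error"
    )
  }
  extra <- setdiff(names(raw), payments_schema)
  if (length(extra) > 0) {
    warn(paste0("ignoring unknown column(s): ", paste(extra, collapse = ", ")))
  }
  raw <- raw[, payments_schema]
  raw$vat_basis[is.na(raw$vat_basis) | raw$vat_basis == ""] <- "unknown"

  problems <- character(0)
  bad_amount <- which(!amount_ok(raw$amount_gbp))
  if (length(bad_amount) > 0) {
    problems <- c(problems, sprintf(
      "row %d: invalid amount %s", bad_amount, dQuote(raw$amount_gbp[bad_amount])
    ))
  }
  bad_cat <- which(!raw$category %in% payment_categories())
  if (length(bad_cat) > 0) {
    problems <- c(problems, sprintf(
      "row %d: unknown category %s", bad_cat, dQuote(raw$category[bad_cat])
    ))
  }
  bad_basis <- which(!raw$vat_basis %in% c("inclusive", "exclusive", "unknown"))
  if (length(bad_basis) > 0) {
    problems <- c(problems, sprintf(
      "row %d: unknown vat_basis %s", bad_basis, dQuote(raw$vat_basis[bad_basis])
    ))
  }
  if (length(problems) > 0) {
    abort(
      paste0(
        "payments file failed validation:\n",
        paste0("  ", problems, collapse = "\n")
      ),
      class = "paynet_validation_error"
    )
  }
  tibble::tibble(
    payment_id = seq_len(nrow(raw)),
    company = raw$company,
    institution_name = raw$institution_name,
    institution_location = raw$institution_location,
    category = raw$category,
    amount_gbp = as.numeric(raw$amount_gbp),
    vat_basis = raw$vat_basis
  )
}

#' Read and validate a practice registry
#'
#' Expects columns `practice_code`, `name`, `address`, `postcode`,
#' `region`, `n_registered`, `n_over65`, `imd_decile`. Practice codes must
#' be unique; regions must be English regions; deciles must lie in 1..10.
#'
#' @param path path to the CSV file.
#' @return tibble of practice records.
#' @export
read_registry <- function(path) {
  if (!file.exists(path)) abort(paste0("no such file: ", path))
  raw <- read.csv(path, colClasses = "character", check.names = FALSE)
  missing_cols <- setdiff(registry_schema, names(raw))
  if (length(missing_cols) > 0) {
    abort(
      paste0("registry lacks required column(s): ",
        paste(missing_cols, collapse = ", ")
      ),
      class = "paynet_schema_error"
    )
  }
  out <- tibble::tibble(
    practice_code = raw$practice_code,
    name = raw$name,
    address = raw$address,
    postcode = raw$postcode,
    region = raw$region,
    n_registered = as.integer(raw$n_registered),
    n_over65 = as.integer(raw$n_over65),
    imd_decile = as.integer(raw$imd_decile)
  )
  if (anyDuplicated(out$practice_code)) {
    abort("registry practice codes are not unique", class = "paynet_validation_error")
  }
  bad <- which(!out$region %in% english_regions())
  if (length(bad) > 0) {
    abort(
      paste0("unknown region(s) in rows ", paste(head(bad, 5), collapse = ", ")),
      class = "paynet_validation_error"
    )
  }
  if (any(is.na(out$imd_decile)) || any(out$imd_decile < 1 | out$imd_decile > 10)) {
    abort("imd_decile must lie in 1..10", class = "paynet_validation_error")
  }
  out
}

#' VAT handling policy
#'
#' How disclosed amounts are brought onto a common VAT-exclusive basis.
#' Amounts reported VAT-inclusive are divided by `1 + rate` and rounded
#' half-up to pence; exclusive amounts pass through unchanged. A company
#' listed in `per_company_basis` overrides the per-row `vat_basis`.
#'
#' @param rate VAT rate as a fraction (UK standard rate 0.20).
#' @param per_company_basis optional named character vector mapping company
#'   name to `"inclusive"` or `"exclusive"`.
#' @param unknown_policy what to do with rows whose basis resolves to
#'   `"unknown"`: `"assume_exclusive"` (default; amounts untouched),
#'   `"assume_inclusive"`, or `"reject"`.
#' @return object of class `vat_policy`.
#' @export
vat_policy <- function(rate = 0.20,
                       per_company_basis = NULL,
                       unknown_policy = c("assume_exclusive", "assume_inclusive", "reject")) {
  unknown_policy <- match.arg(unknown_policy)
  if (!is.numeric(rate) || rate < 0 || rate >= 1) {
    abort("VAT rate must lie in [0, 1)", class = "paynet_config_error")
  }
  if (!is.null(per_company_basis)) {
    if (is.null(names(per_company_basis)) ||
      !all(per_company_basis %in% c("inclusive", "exclusive"))) {
      abort("per_company_basis must be a named vector of inclusive/exclusive",
        class = "paynet_config_error"
      )
    }
  }
  structure(
    list(
      rate = rate, per_company_basis = per_company_basis,
      unknown_policy = unknown_policy
    ),
    class = "vat_policy"
  )
}

#' Normalize payment amounts to a VAT-exclusive basis
#'
#' Divides VAT-inclusive amounts by `1 + rate`, rounding half-up to pence,
#' and marks every row `vat_basis = "exclusive"`. Idempotent: applying it a
#' second time changes nothing. The adjusted total never exceeds the input
#' total.
#'
#' @param payments payments tibble (see [read_payments()]).
#' @param policy a [vat_policy()].
#' @return payments tibble on the exclusive basis.
#' @examples
#' p <- tibble::tibble(
#'   payment_id = 1:2, company = c("A", "B"),
#'   institution_name = "X", institution_location = "Y",
#'   category = "donation_grant", amount_gbp = c(120, 100),
#'   vat_basis = c("inclusive", "exclusive")
#' )
#' normalize_vat(p, vat_policy())$amount_gbp # 100, 100
#' @export
normalize_vat <- function(payments, policy = vat_policy()) {
  stopifnot(inherits(policy, "vat_policy"))
  basis <- payments$vat_basis
  if (!is.null(policy$per_company_basis)) {
    override <- policy$per_company_basis[payments$company]
    basis <- ifelse(is.na(override), basis, override)
  }
  unk <- basis == "unknown"
  if (any(unk)) {
    if (policy$unknown_policy == "reject") {
      abort(
        paste0(
          "unknown VAT basis for company(ies): ",
          paste(sort(unique(payments$company[unk])), collapse = ", ")
        ),
        class = "paynet_vat_error"
      )
    }
    basis[unk] <- if (policy$unknown_policy == "assume_inclusive") "inclusive" else "exclusive"
  }
  inc <- basis == "inclusive"
  payments$amount_gbp[inc] <- round_half_up(
    payments$amount_gbp[inc] / (1 + policy$rate), 2
  )
  payments$vat_basis <- "exclusive"
  payments
}

#' Candidate recipient strings of each payment
#'
#' Recipients may be recorded in either the institution-name or the
#' institution-location field, so both are considered, name first. Blank
#' candidates are dropped; a payment with both fields blank is flagged
#' unlinkable at source.
#'
#' @param payments payments tibble.
#' @return tibble `payment_id`, `candidate` (string), `source`
#'   (`"institution_name"` or `"institution_location"`), `priority` (1 =
#'   name). Payments with no usable candidate are absent; see
#'   `attr(, "unlinkable")` for their ids.
#' @export
recipient_candidates <- function(payments) {
  long <- tibble::tibble(
    payment_id = rep(payments$payment_id, 2),
    candidate = c(payments$institution_name, payments$institution_location),
    source = rep(c("institution_name", "institution_location"),
      each = nrow(payments)
    ),
    priority = rep(c(1L, 2L), each = nrow(payments))
  )
  long <- long[!is.na(long$candidate) & trimws(long$candidate) != "", ]
  long <- long[order(long$payment_id, long$priority), ]
  unlinkable <- setdiff(payments$payment_id, long$payment_id)
  structure(long, unlinkable = unlinkable)
}
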