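# fixed abbreviation table used by the normalizer; "st" is resolved to
# "street" (the street/saint ambiguity is settled in favour of street)
abbrev_table <- function() {
  c(
    rd = "road", st = "street", surg = "surgery", dr = "doctor",
    hc = "health centre", med = "medical", ave = "avenue", ln = "lane"
  )
}

#' Canonicalize free-text names and addresses
#'
#' Casefolds, strips punctuation, collapses whitespace and expands a fixed
#' table of abbreviations (`rd` to road, `st` to street, `surg` to surgery,
#' `dr` to doctor, `hc` to health centre, `med` to medical, `ave` to
#' avenue, `ln` to lane). Idempotent: a second application is the identity.
#'
#' @param x character vector (empty in, empty out).
#' @return canonical lower-case strings.
#' @examples
#' normalize_text("The Old-Surgery,  LEEDS")
#' normalize_text("HIGH ST. SURG")
#' @export
normalize_text <- function(x) {
  out <- tolower(x)
  out <- gsub("[^a-z0-9]+", " ", out)
  out <- trimws(gsub(" +", " ", out))
  tab <- abbrev_table()
  vapply(strsplit(out, " ", fixed = TRUE), function(tok) {
    if (length(tok) == 0) return("")
    hit <- match(tok, names(tab))
    tok[!is.na(hit)] <- tab[hit[!is.na(hit)]]
    paste(tok, collapse = " ")
  }, character(1))
}

#' Canonicalize a UK postcode
#'
#' Uppercases and rewrites with a single internal space before the final
#' three characters (the inward code).
#'
#' @param x character vector of postcodes.
#' @return canonical postcodes; `NA` stays `NA`.
#' @examples
#' normalize_postcode("ls12  3ab")
#' @export
normalize_postcode <- function(x) {
  compact <- gsub("[^A-Za-z0-9]", "", toupper(x))
  ifelse(is.na(x) | nchar(compact) < 5, NA_character_,
    paste(
      substr(compact, 1, nchar(compact) - 3),
      substr(compact, nchar(compact) - 2, nchar(compact))
    )
  )
}

# first UK-shaped postcode found in a raw string, else NA
extract_postcode <- function(x) {
  out <- rep(NA_character_, length(x))
  hit <- regexpr("[A-Za-z]{1,2}[0-9][0-9A-Za-z]?[ ]*[0-9][A-Za-z]{2}\\b", x)
  out[hit > 0] <- regmatches(x, hit)
  normalize_postcode(out)
}

#' Token-set similarity of two strings
#'
#' Fuzzy similarity in `[0, 1]` robust to word order and partial overlap:
#' both strings are tokenised, and the best pairwise Levenshtein similarity
#' among the sorted common-token string and the two "common + remainder"
#' strings is returned (the classic token-set ratio). Identical token sets
#' give 1 regardless of order.
#'
#' @param a single string (compared after [normalize_text()] by callers).
#' @param b character vector of strings to compare against.
#' @return numeric vector of similarities in `[0, 1]`.
#' @examples
#' token_set_ratio("old surgery leeds", "leeds old surgery")
#' @export
token_set_ratio <- function(a, b) {
  ta <- unique(strsplit(a, " ", fixed = TRUE)[[1]])
  lev_sim <- function(u, v) {
    if (nchar(u) == 0 && nchar(v) == 0) return(1)
    1 - as.numeric(adist(u, v)) / max(nchar(u), nchar(v))
  }
  vapply(b, function(bi) {
    tb <- unique(strsplit(bi, " ", fixed = TRUE)[[1]])
    common <- sort(intersect(ta, tb))
    rest_a <- sort(setdiff(ta, tb))
    rest_b <- sort(setdiff(tb, ta))
    s0 <- paste(common, collapse = " ")
    s1 <- paste(c(common, rest_a), collapse = " ")
    s2 <- paste(c(common, rest_b), collapse = " ")
    max(lev_sim(s0, s1), lev_sim(s0, s2), lev_sim(s1, s2))
  }, numeric(1), USE.NAMES = FALSE)
}

#' Exclusion accounting for unlinked payments
#'
#' Builds the report that summarises how many payments, how much value and
#' how many distinct recipient practices were dropped because recipients
#' could not be linked to a practice code. Percentages are rounded half-up
#' to 2 decimals for the count-based figures and 1 decimal for the value
#' share. Final-sample figures (totals minus exclusions) are derived
#' pence-exactly.
#'
#' @param n_payments_total,n_payments_excluded payment counts.
#' @param value_total_gbp,value_excluded_gbp GBP values (2 dp).
#' @param n_practices_total,n_practices_excluded distinct recipient counts.
#' @return object of class `exclusion_report`.
#' @examples
#' exclusion_report(2945, 198, 2726017.77, 166351.74, 1790, 147)
#' @export
exclusion_report <- function(n_payments_total, n_payments_excluded,
                             value_total_gbp, value_excluded_gbp,
                             n_practices_total, n_practices_excluded) {
  if (n_payments_excluded > n_payments_total ||
    value_excluded_gbp > value_total_gbp ||
    n_practices_excluded > n_practices_total) {
    abort("excluded figures cannot exceed totals", class = "paynet_report_error")
  }
  structure(
    list(
      n_payments_total = n_payments_total,
      n_excluded = n_payments_excluded,
      pct_excluded = round_half_up(100 * n_payments_excluded / n_payments_total, 2),
      value_total_gbp = value_total_gbp,
      value_excluded_gbp = value_excluded_gbp,
      pct_value_excluded = round_half_up(100 * value_excluded_gbp / value_total_gbp, 1),
      n_recipient_practices_total = n_practices_total,
      n_practices_excluded = n_practices_excluded,
      pct_practices_excluded = round_half_up(
        100 * n_practices_excluded / n_practices_total, 2
      ),
      n_payments_final = n_payments_total - n_payments_excluded,
      value_final_gbp = (as_pence(value_total_gbp) - as_pence(value_excluded_gbp)) / 100,
      n_practices_final = n_practices_total - n_practices_excluded
    ),
    class = "exclusion_report"
  )
}

#' @export
print.exclusion_report <- function(x, ...) {
  cat(sprintf(
    paste0(
      "Exclusion report\n",
      "  payments:  %d of %d excluded (%.2f%%)\n",
      "  value:     £%.2f of £%.2f excluded (%.1f%%)\n",
      "  practices: %d of %d excluded (%.2f%%)\n",
      "  final sample: %d payments, £%.2f, %d practices\n"
    ),
    x$n_excluded, x$n_payments_total, x$pct_excluded,
    x$value_excluded_gbp, x$value_total_gbp, x$pct_value_excluded,
    x$n_practices_excluded, x$n_recipient_practices_total,
    x$pct_practices_excluded,
    x$n_payments_final, x$value_final_gbp, x$n_practices_final
  ))
  invisible(x)
}

#' Link free-text payment recipients to practice codes
#'
#' Deterministic two-stage matcher. Stage one tries exact matches of each
#' normalized candidate string (institution name first, then location)
#' against, in order of specificity: registry name plus postcode, unique
#' registry name, normalized address plus postcode, and unique normalized
#' address. Stage two computes the token-set similarity of the best
#' candidate against registry names in the same postcode district (the
#' outward half of the payment's extractable postcode) and accepts the
#' highest similarity at or above `fuzzy_threshold`; ties break to the
#' lexicographically smallest practice code. Everything else is unmatched
#' and feeds the exclusion report.
#'
#' @param payments payments tibble (see [read_payments()]).
#' @param registry practice registry tibble.
#' @param fuzzy_threshold acceptance threshold for stage two (default 0.90).
#' @return object of class `linkage_result`: list with `linked` (matched
#'   payments with `practice_code`, `method`, `similarity`, `matched_on`),
#'   `matches` (the same columns for every payment, unmatched included) and
#'   `report` (an [exclusion_report()]).
#' @export
link_payments <- function(payments, registry, fuzzy_threshold = 0.90) {
  if (nrow(registry) == 0) abort("registry is empty", class = "paynet_linkage_error")
  if (anyDuplicated(registry$practice_code)) {
    abort("registry practice codes are not unique", class = "paynet_linkage_error")
  }
  if (fuzzy_threshold < 0 || fuzzy_threshold > 1) {
    abort("fuzzy_threshold must lie in [0, 1]", class = "paynet_config_error")
  }

  reg_name <- normalize_text(registry$name)
  reg_pc <- normalize_postcode(registry$postcode)
  reg_pc_key <- tolower(gsub(" ", "", reg_pc))
  reg_loc <- normalize_text(paste(registry$address, registry$postcode))
  reg_addr <- normalize_text(registry$address)
  reg_district <- sub(" .*", "", reg_pc)

  unique_keys <- function(keys) {
    keep <- !(duplicated(keys) | duplicated(keys, fromLast = TRUE)) &
      !is.na(keys) & keys != ""
    list(keys = keys[keep], code = registry$practice_code[keep])
  }
  k_name_pc <- unique_keys(paste(reg_name, reg_pc_key))
  k_name <- unique_keys(reg_name)
  k_loc <- unique_keys(reg_loc)
  k_addr <- unique_keys(reg_addr)

  cand <- recipient_candidates(payments)
  cand$nc <- normalize_text(cand$candidate)

  # payment-level postcode: first extractable across candidates in priority order
  pc_by_cand <- extract_postcode(cand$candidate)
  first_pc <- tapply(pc_by_cand, cand$payment_id, function(v) {
    v <- v[!is.na(v)]
    if (length(v) == 0) NA_character_ else v[1]
  })
  pay_pc <- rep(NA_character_, nrow(payments))
  pay_pc[as.integer(names(first_pc))] <- as.character(first_pc)
  pay_pc_key <- tolower(gsub(" ", "", pay_pc))

  n_pay <- nrow(payments)
  code <- rep(NA_character_, n_pay)
  method <- rep("unmatched", n_pay)
  similarity <- rep(NA_real_, n_pay)
  matched_on <- rep(NA_character_, n_pay)

  try_stage <- function(cand_keys, lookup) {
    idx <- match(cand_keys, lookup$keys)
    hit <- which(!is.na(idx) & is.na(code[cand$payment_id]))
    # candidates are ordered by (payment, priority); first hit per payment wins
    hit <- hit[!duplicated(cand$payment_id[hit])]
    pid <- cand$payment_id[hit]
    code[pid] <<- lookup$code[idx[hit]]
    method[pid] <<- "exact_normalized"
    similarity[pid] <<- 1
    matched_on[pid] <<- cand$source[hit]
  }
  try_stage(paste(cand$nc, pay_pc_key[cand$payment_id]), k_name_pc)
  try_stage(cand$nc, k_name)
  try_stage(cand$nc, k_loc)
  try_stage(cand$nc, k_addr)

  # stage two: postcode-district-gated fuzzy match of the best candidate
  best <- cand[!duplicated(cand$payment_id), ]
  todo <- best[is.na(code[best$payment_id]) & !is.na(pay_pc[best$payment_id]), ]
  for (i in seq_len(nrow(todo))) {
    pid <- todo$payment_id[i]
    rows <- which(reg_district == sub(" .*", "", pay_pc[pid]))
    if (length(rows) == 0) next
    sims <- token_set_ratio(todo$nc[i], reg_name[rows])
    ok <- sims >= fuzzy_threshold
    if (!any(ok)) next
    top <- max(sims[ok])
    codes_top <- sort(registry$practice_code[rows[ok & sims >= top - 1e-12]])
    code[pid] <- codes_top[1]
    method[pid] <- "fuzzy"
    similarity[pid] <- top
    matched_on[pid] <- todo$source[i]
  }

  matches <- payments
  matches$practice_code <- code
  matches$method <- method
  matches$similarity <- similarity
  matches$matched_on <- matched_on

  unmatched <- is.na(code)
  # distinct recipient identities: practice codes for matched payments,
  # deduplicated normalized best-candidate strings for the rest
  best_nc <- rep("<blank>", n_pay)
  best_nc[best$payment_id] <- best$nc
  recipients_matched <- unique(code[!unmatched])
  recipients_unmatched <- unique(best_nc[unmatched])
  report <- exclusion_report(
    n_payments_total = n_pay,
    n_payments_excluded = sum(unmatched),
    value_total_gbp = sum(as_pence(payments$amount_gbp)) / 100,
    value_excluded_gbp = sum(as_pence(payments$amount_gbp[unmatched])) / 100,
    n_practices_total = length(recipients_matched) + length(recipients_unmatched),
    n_practices_excluded = length(recipients_unmatched)
  )
  structure(
    list(
      linked = matches[!unmatched, ],
      matches = matches,
      report = report
    ),
    class = "linkage_result"
  )
}
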