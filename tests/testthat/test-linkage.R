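test_that("normalize_text casefolds, strips punctuation and expands abbreviations", {
  expect_identical(normalize_text("The Old-Surgery,  LEEDS"), "the old surgery leeds")
  expect_identical(normalize_text("HIGH ST. SURG"), "high street surgery")
  expect_identical(normalize_text(""), "")
})

test_that("normalize_text is idempotent on random strings", {
  set.seed(1)
  alphabet <- c(letters, LETTERS, 0:9, " ", ".", ",", "-", "'", "/")
  for (i in 1:50) {
    s <- paste(sample(alphabet, sample(0:40, 1), replace = TRUE), collapse = "")
    once <- normalize_text(s)
    expect_identical(normalize_text(once), once)
  }
})

test_that("postcodes canonicalise to upper case with one internal space", {
  expect_identical(normalize_postcode("ls12  3ab"), "LS12 3AB")
  expect_identical(normalize_postcode("EC1A1BB"), "EC1A 1BB")
  expect_true(is.na(normalize_postcode("xyz")))
})

test_that("token-set similarity is order-insensitive and bounded", {
  expect_equal(token_set_ratio("old surgery leeds", "leeds old surgery"), 1)
  expect_equal(token_set_ratio("abc", "abc"), 1)
  s <- token_set_ratio("old surgery leeds", "new practice york")
  expect_gte(s, 0)
  expect_lt(s, 0.6)
})

test_that("exact normalized matches link with similarity 1", {
  reg <- tibble::tibble(
    practice_code = c("A00001", "B00002"),
    name = c("Old Surgery", "Mill Practice"),
    address = c("1 High Street, Leeds", "2 Low Road, York"),
    postcode = c("LS1 2AB", "YO1 9ZZ"),
    region = c("London", "London"),
    n_registered = c(5000L, 6000L), n_over65 = c(800L, 900L),
    imd_decile = c(5L, 6L)
  )
  pay <- tibble::tibble(
    payment_id = 1:2, company = "X",
    institution_name = c("OLD SURGERY", "NO SUCH PLACE"),
    institution_location = c("", "NOWHERE AT ALL"),
    category = "donation_grant", amount_gbp = c(10, 20),
    vat_basis = "exclusive"
  )
  res <- link_payments(pay, reg)
  expect_identical(res$matches$practice_code[1], "A00001")
  expect_identical(res$matches$method[1], "exact_normalized")
  expect_equal(res$matches$similarity[1], 1)
  expect_identical(res$matches$method[2], "unmatched")
  expect_true(is.na(res$matches$practice_code[2]))
})

test_that("light-noise synthetic payments link to their truth codes with 100% recall", {
  b <- small_bundle(seed = 4, name_noise_rate = 0.3, unmatchable_rate = 0)
  res <- link_payments(normalize_vat(b$payments), b$registry)
  joined <- dplyr::inner_join(res$matches, b$truth, by = "payment_id")
  expect_identical(res$report$n_excluded, 0L)
  expect_true(all(joined$practice_code.x == joined$practice_code.y))
})

test_that("unmatched fraction tracks the unmatchable rate and heavy rows never match", {
  b <- small_bundle(seed = 6, unmatchable_rate = 0.12)
  res <- link_payments(normalize_vat(b$payments), b$registry)
  joined <- dplyr::inner_join(res$matches, b$truth, by = "payment_id")
  heavy <- joined$corruption == "heavy"
  expect_true(all(is.na(joined$practice_code.x[heavy])))
  expect_true(all(joined$practice_code.x[!heavy] == joined$practice_code.y[!heavy]))
  n <- nrow(joined)
  expect_lt(
    abs(res$report$n_excluded / n - 0.12),
    3 * sqrt(0.12 * 0.88 / n)
  )
})

test_that("value is conserved pence-exactly through linkage", {
  b <- small_bundle(seed = 7)
  pay <- normalize_vat(b$payments)
  res <- link_payments(pay, b$registry)
  r <- res$report
  expect_identical(
    as_pence(r$value_total_gbp),
    as_pence(r$value_excluded_gbp) + sum(as_pence(res$linked$amount_gbp))
  )
  expect_identical(as_pence(r$value_total_gbp), sum(as_pence(pay$amount_gbp)))
})

test_that("lowering the fuzzy threshold never decreases the match count", {
  b <- small_bundle(seed = 9, name_noise_rate = 0.35, unmatchable_rate = 0.05)
  pay <- normalize_vat(b$payments)
  matched <- sapply(c(0.99, 0.9, 0.7, 0.5), function(th) {
    nrow(link_payments(pay, b$registry, fuzzy_threshold = th)$linked)
  })
  expect_true(all(diff(matched) >= 0))
})

test_that("exclusion report reproduces ratio arithmetic at the published precision", {
  r <- exclusion_report(
    n_payments_total = 2945, n_payments_excluded = 198,
    value_total_gbp = 2726017.77, value_excluded_gbp = 166351.74,
    n_practices_total = 1790, n_practices_excluded = 147
  )
  expect_equal(r$pct_excluded, 6.72)
  expect_equal(r$pct_value_excluded, 6.1)
  expect_equal(r$pct_practices_excluded, 8.21)
  expect_equal(r$n_payments_final, 2747)
  expect_equal(r$value_final_gbp, 2559666.03)
  expect_equal(r$n_practices_final, 1643)
  expect_error(
    exclusion_report(10, 11, 100, 5, 5, 1),
    class = "paynet_report_error"
  )
})

test_that("an empty registry is an error", {
  pay <- tibble::tibble(
    payment_id = 1L, company = "X", institution_name = "A",
    institution_location = "B", category = "donation_grant",
    amount_gbp = 10, vat_basis = "exclusive"
  )
  expect_error(
    link_payments(pay, tibble::tibble(practice_code = character(0))),
    class = "paynet_linkage_error"
  )
})
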