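test_that("registry has the configured size, unique codes and valid fields", {
  reg <- generate_registry(generator_config(n_practices = 10, seed = 1))
  expect_identical(nrow(reg), 10L)
  expect_identical(length(unique(reg$practice_code)), 10L)
  expect_true(all(grepl("^[A-Z][0-9]{5}$", reg$practice_code)))
  expect_true(all(reg$region %in% english_regions()))
  expect_true(all(reg$n_registered >= 500))
  expect_true(all(reg$n_over65 >= 0 & reg$n_over65 <= reg$n_registered))
  expect_true(all(reg$imd_decile %in% 1:10))
})

test_that("generation is deterministic under a fixed seed", {
  cfg <- small_config(seed = 42)
  b1 <- simulate_bundle(cfg)
  b2 <- simulate_bundle(cfg)
  expect_identical(b1$payments, b2$payments)
  expect_identical(b1$registry, b2$registry)
  expect_identical(b1$truth, b2$truth)
})

test_that("uniform region weights give per-region counts within binomial bounds", {
  n <- 50000
  reg <- generate_registry(generator_config(n_practices = n, seed = 7))
  counts <- table(factor(reg$region, levels = english_regions()))
  # 99% two-sided binomial interval around n/9, Bonferroni-free per-region check
  bounds <- qbinom(c(0.005, 0.995), n, 1 / 9)
  expect_true(all(counts >= bounds[1] & counts <= bounds[2]))
})

test_that("invalid configurations are rejected", {
  expect_error(generator_config(n_practices = 0), class = "paynet_config_error")
  expect_error(
    generator_config(region_weights = setNames(rep(0.5, 2), english_regions()[1:2])),
    class = "paynet_config_error"
  )
  expect_error(generator_config(unmatchable_rate = 1.2), class = "paynet_config_error")
  cfg <- generator_config(
    n_practices = 10,
    dominant_donor = list(n_payments = 100, n_practices = 50), seed = 1
  )
  expect_error(generate_payments(generate_registry(cfg), cfg),
    class = "paynet_config_error"
  )
})

test_that("dominant donor structure and truth table are as configured", {
  b <- small_bundle(seed = 3)
  truth_joined <- dplyr::inner_join(b$payments, b$truth, by = "payment_id")
  dom <- truth_joined[truth_joined$company == "Company 01", ]
  expect_identical(nrow(dom), 80L)
  expect_identical(length(unique(dom$practice_code)), 50L)
  # truth completeness: exactly one code per payment, all codes in registry
  expect_identical(nrow(b$truth), nrow(b$payments))
  expect_true(all(b$truth$practice_code %in% b$registry$practice_code))
})

test_that("heavy-corruption fraction tracks unmatchable_rate within binomial error", {
  b <- simulate_bundle(small_config(seed = 5, unmatchable_rate = 0.10))
  n <- nrow(b$truth)
  frac <- mean(b$truth$corruption == "heavy")
  expect_lt(abs(frac - 0.10), 3 * sqrt(0.1 * 0.9 / n))
})

test_that("payment values respect the floor and carry exactly two decimals", {
  b <- small_bundle(seed = 2)
  expect_true(all(b$payments$amount_gbp >= 8))
  expect_equal(b$payments$amount_gbp, round_half_up(b$payments$amount_gbp, 2))
})

test_that("default calibration recovers the published value quartiles within 10%", {
  cfg <- generator_config(seed = 11)
  reg <- generate_registry(cfg)
  vals <- c()
  s <- 11
  while (length(vals) < 50000) {
    s <- s + 1
    cfg_s <- generator_config(seed = s)
    b <- generate_payments(reg, cfg_s)
    pay <- normalize_vat(b$payments, vat_policy())
    vals <- c(vals, pay$amount_gbp)
  }
  q <- quantile(vals, c(0.25, 0.5, 0.75), type = 7)
  expect_lt(abs(q[[1]] - 170) / 170, 0.10)
  expect_lt(abs(q[[2]] - 320) / 320, 0.10)
  expect_lt(abs(q[[3]] - 869) / 869, 0.10)
})

test_that("written bundles round-trip through the readers", {
  b <- small_bundle(seed = 8)
  dir <- withr::local_tempdir()
  write_bundle(b, dir)
  pay <- read_payments(file.path(dir, "payments.csv"))
  reg <- read_registry(file.path(dir, "registry.csv"))
  expect_identical(nrow(pay), nrow(b$payments))
  expect_equal(pay$amount_gbp, b$payments$amount_gbp)
  expect_identical(pay$company, b$payments$company)
  expect_identical(reg, b$registry)
})
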