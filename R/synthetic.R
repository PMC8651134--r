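#' Configuration for the synthetic disclosure generator
#'
#' Bundles every tunable of the synthetic-data module. The defaults are the
#' documented calibration: they reproduce the published 2015 summary
#' statistics of drug-company payments to English general practices —
#' a median single-payment value of £320 with IQR £170–£869, one dominant
#' donor making about 1,000 payments to about 780 practices, ordinary
#' donors making mostly no more than ~81 payments, and three-quarters of
#' payment-receiving practices receiving at most two payments.
#'
#' @param n_companies number of donor companies (default 34, the size of
#'   the published final sample).
#' @param n_practices number of practices in the registry (default 7,500,
#'   approximately the English practice population).
#' @param region_weights named probability vector over [english_regions()];
#'   default uniform. Must sum to 1 within 1e-9.
#' @param lognormal_mu,lognormal_sigma log-scale location and upper-tail
#'   scale of the single-payment GBP value distribution. Values are drawn
#'   as a split (two-piece) lognormal: `exp(mu + sigma_lower * z)` for
#'   `z < 0` and `exp(mu + sigma * z)` for `z >= 0`, with `z` standard
#'   normal. The published quartiles are asymmetric on the log scale
#'   (`log(320/170) != log(869/320)`), so a single-sigma lognormal cannot
#'   match all three; the split defaults solve `exp(mu) = 320`,
#'   `exp(mu - 0.6745 sigma_lower) = 170` and
#'   `exp(mu + 0.6745 sigma) = 869` exactly.
#' @param lognormal_sigma_lower lower-tail scale (see above).
#' @param category_mix named probabilities over [payment_categories()].
#' @param dominant_donor list with `n_payments` and `n_practices`: the
#'   single large donor (defaults 1,000 payments across 780 distinct
#'   practices).
#' @param ordinary_donor_payments list with `meanlog`, `sdlog`, `max`:
#'   per-company payment counts for the non-dominant donors are drawn from
#'   a rounded lognormal truncated to `[1, max]`. Default median 14.5.
#' @param practice_popularity_alpha tail exponent of the Zipf-like practice
#'   popularity law used to select recipient practices (default 0.8; see
#'   the methods vignette for the calibration).
#' @param unmatchable_rate fraction of payments whose recipient strings are
#'   corrupted beyond any linkage (default 0.05).
#' @param name_noise_rate fraction of payments receiving light, recoverable
#'   noise (case, punctuation, abbreviations; default 0.20).
#' @param vat_inclusive_rate probability that a company reports its amounts
#'   VAT-inclusive, in which case its generated (VAT-exclusive) amounts are
#'   multiplied by 1.2 and flagged `inclusive` (default 0.15).
#' @param over65_beta_params shape parameters of the Beta distribution of
#'   the share of registered patients aged over 65 (default c(5, 24),
#'   mean ≈ 0.17).
#' @param patients_lognormal `c(meanlog, sdlog)` of registered-patient
#'   counts (default median 7,000), floored at 500.
#' @param value_floor minimum single-payment value in GBP (default £8, the
#'   published minimum).
#' @param seed integer seed; all generator randomness derives from it.
#' @return object of class `generator_config` (a validated list).
#' @examples
#' cfg <- generator_config(n_companies = 5, n_practices = 100, seed = 1)
#' cfg$lognormal_sigma
#' @export
generator_config <- function(n_companies = 34,
                             n_practices = 7500,
                             region_weights = NULL,
                             lognormal_mu = log(320),
                             lognormal_sigma = log(869 / 320) / 0.6745,
                             lognormal_sigma_lower = log(320 / 170) / 0.6745,
                             category_mix = c(
                               donation_grant = 0.60,
                               event_contribution = 0.37,
                               service_consultancy = 0.03
                             ),
                             dominant_donor = list(n_payments = 1000, n_practices = 780),
                             ordinary_donor_payments = list(
                               meanlog = log(14.5), sdlog = 2.0, max = 400
                             ),
                             practice_popularity_alpha = 0.8,
                             unmatchable_rate = 0.05,
                             name_noise_rate = 0.20,
                             vat_inclusive_rate = 0.15,
                             over65_beta_params = c(5, 24),
                             patients_lognormal = c(meanlog = log(7000), sdlog = 0.45),
                             value_floor = 8,
                             seed = 1L) {
  if (is.null(region_weights)) {
    region_weights <- setNames(rep(1 / 9, 9), english_regions())
  }
  check_count <- function(x, nm) {
    if (!is.numeric(x) || length(x) != 1 || is.na(x) || x < 1 || x != floor(x)) {
      abort(sprintf("`%s` must be a positive integer, got %s", nm, deparse(x)),
        class = "paynet_config_error"
      )
    }
  }
  check_rate <- function(x, nm) {
    if (!is.numeric(x) || length(x) != 1 || is.na(x) || x < 0 || x > 1) {
      abort(sprintf("`%s` must lie in [0, 1]", nm), class = "paynet_config_error")
    }
  }
  check_probs <- function(x, nm, names_needed) {
    if (!setequal(names(x), names_needed) || any(x < 0) ||
      abs(sum(x) - 1) > 1e-9) {
      abort(
        sprintf("`%s` must be named probabilities over {%s} summing to 1",
          nm, paste(names_needed, collapse = ", ")
        ),
        class = "paynet_config_error"
      )
    }
  }
  check_count(n_companies, "n_companies")
  check_count(n_practices, "n_practices")
  check_count(dominant_donor$n_payments, "dominant_donor$n_payments")
  check_count(dominant_donor$n_practices, "dominant_donor$n_practices")
  if (dominant_donor$n_practices > dominant_donor$n_payments) {
    abort("dominant donor cannot pay more practices than it makes payments",
      class = "paynet_config_error"
    )
  }
  check_probs(region_weights, "region_weights", english_regions())
  check_probs(category_mix, "category_mix", payment_categories())
  check_rate(unmatchable_rate, "unmatchable_rate")
  check_rate(name_noise_rate, "name_noise_rate")
  check_rate(vat_inclusive_rate, "vat_inclusive_rate")
  if (unmatchable_rate + name_noise_rate > 1) {
    abort("unmatchable_rate + name_noise_rate must not exceed 1",
      class = "paynet_config_error"
    )
  }
  if (lognormal_sigma <= 0 || lognormal_sigma_lower <= 0 ||
    practice_popularity_alpha < 0 || value_floor < 0) {
    abort("lognormal sigmas must be > 0; alpha and value_floor must be >= 0",
      class = "paynet_config_error"
    )
  }
  if (any(over65_beta_params <= 0) || length(over65_beta_params) != 2) {
    abort("over65_beta_params must be two positive shapes",
      class = "paynet_config_error"
    )
  }
  structure(
    list(
      n_companies = as.integer(n_companies),
      n_practices = as.integer(n_practices),
      region_weights = region_weights,
      lognormal_mu = lognormal_mu,
      lognormal_sigma = lognormal_sigma,
      lognormal_sigma_lower = lognormal_sigma_lower,
      category_mix = category_mix,
      dominant_donor = dominant_donor,
      ordinary_donor_payments = ordinary_donor_payments,
      practice_popularity_alpha = practice_popularity_alpha,
      unmatchable_rate = unmatchable_rate,
      name_noise_rate = name_noise_rate,
      vat_inclusive_rate = vat_inclusive_rate,
      over65_beta_params = over65_beta_params,
      patients_lognormal = patients_lognormal,
      value_floor = value_floor,
      seed = as.integer(seed)
    ),
    class = "generator_config"
  )
}

# word stock for synthetic place/practice names; two-part combinations give
# enough variety that name collisions stay rare (and the few that occur are
# realistic: real registries contain many a "The Surgery")
place_roots <- function() {
  c(
    "Ash", "Birch", "Bram", "Brook", "Burn", "Carl", "Ches", "Clif", "Croft",
    "Dale", "East", "Elm", "Fair", "Fern", "Grange", "Green", "Hart", "Hazel",
    "High", "Holly", "Holm", "Kirk", "Lang", "Lime", "Lind", "Maple", "Mead",
    "Mill", "Moor", "North", "Oak", "Orchard", "Park", "Pen", "Rose", "Rydal",
    "Stan", "Stone", "Thorn", "Well", "West", "Willow", "Wood", "Wyke", "York"
  )
}

place_suffixes <- function() {
  c(
    "bury", "by", "combe", "dale", "field", "ford", "gate", "ham", "hill",
    "holme", "hurst", "lands", "leigh", "ley", "mead", "mere", "stead",
    "thorpe", "ton", "view", "wick", "wood", "worth"
  )
}

practice_types <- function() {
  c(
    "Surgery", "Medical Practice", "Health Centre", "Medical Centre",
    "Family Practice", "Group Practice"
  )
}

street_types <- function() c("Road", "Street", "Lane", "Avenue", "Way", "Close")

#' Generate a synthetic practice registry
#'
#' Draws `n_practices` practice records: unique codes (one letter plus five
#' digits, the NHS practice-code shape), names and addresses built from a
#' fixed word stock, UK-shaped postcodes, regions drawn from
#' `region_weights`, registered-patient counts (lognormal, floored at 500),
#' over-65 patient counts (Beta share of the list size) and a uniform
#' deprivation decile (1 = most deprived).
#'
#' @param config a [generator_config()].
#' @return tibble with columns `practice_code`, `name`, `address`,
#'   `postcode`, `region`, `n_registered`, `n_over65`, `imd_decile`.
#' @examples
#' reg <- generate_registry(generator_config(n_practices = 10, seed = 1))
#' nrow(reg)
#' @export
generate_registry <- function(config) {
  stopifnot(inherits(config, "generator_config"))
  set.seed(config$seed)
  n <- config$n_practices
  if (n > 99999) abort("n_practices exceeds the practice-code space (99,999)")

  code_digits <- sample.int(99999L, n)
  practice_code <- paste0(
    sample(LETTERS, n, replace = TRUE), sprintf("%05d", code_digits)
  )

  place <- paste0(
    sample(place_roots(), n, replace = TRUE),
    sample(place_suffixes(), n, replace = TRUE)
  )
  name <- paste(place, sample(practice_types(), n, replace = TRUE))

  town <- paste0(
    sample(place_roots(), n, replace = TRUE),
    sample(place_suffixes(), n, replace = TRUE)
  )
  address <- paste0(
    sample.int(250L, n, replace = TRUE), " ",
    sample(place_roots(), n, replace = TRUE),
    " ", sample(street_types(), n, replace = TRUE),
    ", ", town
  )

  district <- paste0(
    sample(LETTERS, n, replace = TRUE), sample(LETTERS, n, replace = TRUE),
    sample.int(20L, n, replace = TRUE)
  )
  postcode <- paste0(
    district, " ", sample.int(9L, n, replace = TRUE),
    sample(LETTERS, n, replace = TRUE), sample(LETTERS, n, replace = TRUE)
  )

  region <- sample(names(config$region_weights), n,
    replace = TRUE, prob = config$region_weights
  )
  n_registered <- pmax(
    500L,
    as.integer(round(rlnorm(
      n, config$patients_lognormal[["meanlog"]], config$patients_lognormal[["sdlog"]]
    )))
  )
  share65 <- rbeta(n, config$over65_beta_params[1], config$over65_beta_params[2])
  n_over65 <- as.integer(round(share65 * n_registered))

  tibble::tibble(
    practice_code = practice_code,
    name = name,
    address = address,
    postcode = postcode,
    region = region,
    n_registered = n_registered,
    n_over65 = n_over65,
    imd_decile = sample(1:10, n, replace = TRUE)
  )
}

# light, recoverable corruption: casefolding, stray punctuation and
# abbreviation swaps drawn from the same table the linkage normalizer expands
light_corrupt <- function(x, rng_u) {
  out <- x
  swaps <- rbind(
    c(" ROAD", " RD"),
    c(" STREET", " ST"),
    c(" SURGERY", " SURG"),
    c(" DOCTOR", " DR"),
    c(" MEDICAL", " MED"),
    c(" HEALTH CENTRE", " HC")
  )
  low <- rng_u < 1 / 3
  out[low] <- tolower(out[low])
  mid <- rng_u >= 1 / 3 & rng_u < 2 / 3
  out[mid] <- paste0(sub(" ", "-", out[mid]), ".")
  for (i in seq_len(nrow(swaps))) {
    out <- sub(swaps[i, 1], swaps[i, 2], out, ignore.case = TRUE)
  }
  out
}

#' Generate a synthetic payments table with linkage ground truth
#'
#' Simulates one year of disclosed transfers of value. One dominant donor
#' makes `dominant_donor$n_payments` payments across
#' `dominant_donor$n_practices` distinct practices; the remaining companies
#' draw payment counts from a truncated lognormal and select practices by a
#' Zipf-like popularity law, so most receiving practices get one or two
#' payments. Values are lognormal, rounded half-up to pence and floored at
#' `value_floor`. Recipient strings are rendered from the registry, then a
#' fraction `unmatchable_rate` is corrupted beyond linkage and a further
#' `name_noise_rate` receives light recoverable noise. Companies flagged
#' VAT-inclusive have amounts multiplied by 1.2. The returned truth table
#' records the generating practice of every payment.
#'
#' @param registry output of [generate_registry()].
#' @param config the same [generator_config()].
#' @return object of class `synthetic_bundle`: a list with `payments`
#'   (tibble: `payment_id`, `company`, `institution_name`,
#'   `institution_location`, `category`, `amount_gbp`, `vat_basis`),
#'   `registry`, and `truth` (tibble: `payment_id`, `practice_code`,
#'   `corruption` in none/light/heavy).
#' @examples
#' cfg <- generator_config(
#'   n_companies = 4, n_practices = 50,
#'   dominant_donor = list(n_payments = 30, n_practices = 20), seed = 2
#' )
#' b <- generate_payments(generate_registry(cfg), cfg)
#' nrow(b$payments) == nrow(b$truth)
#' @export
generate_payments <- function(registry, config) {
  stopifnot(inherits(config, "generator_config"))
  if (nrow(registry) == 0) abort("registry is empty")
  if (config$dominant_donor$n_practices > nrow(registry)) {
    abort("dominant_donor$n_practices exceeds the number of practices",
      class = "paynet_config_error"
    )
  }
  set.seed(config$seed + 1L)
  n_pr <- nrow(registry)

  # Zipf-like popularity, randomly assigned to practices
  pop <- (seq_len(n_pr))^(-config$practice_popularity_alpha)
  pop <- sample(pop / sum(pop))

  companies <- sprintf("Company %02d", seq_len(config$n_companies))
  dominant <- companies[1]

  dom <- config$dominant_donor
  dom_distinct <- sample.int(n_pr, dom$n_practices, prob = pop)
  dom_extra <- if (dom$n_payments > dom$n_practices) {
    sample(dom_distinct, dom$n_payments - dom$n_practices, replace = TRUE)
  } else {
    integer(0)
  }
  dom_rows <- c(dom_distinct, dom_extra)

  ord <- config$ordinary_donor_payments
  n_ord <- config$n_companies - 1L
  ord_counts <- pmin(
    pmax(1L, as.integer(round(rlnorm(n_ord, ord$meanlog, ord$sdlog)))),
    as.integer(ord$max)
  )
  ord_rows <- unlist(lapply(ord_counts, function(k) {
    sample.int(n_pr, k, replace = TRUE, prob = pop)
  }), use.names = FALSE)

  practice_row <- c(dom_rows, ord_rows)
  company <- c(
    rep(dominant, length(dom_rows)),
    rep(companies[-1], times = ord_counts)
  )
  n_pay <- length(practice_row)

  z <- stats::rnorm(n_pay)
  sig <- ifelse(z < 0, config$lognormal_sigma_lower, config$lognormal_sigma)
  value <- round_half_up(exp(config$lognormal_mu + sig * z), 2)
  value <- pmax(value, config$value_floor)
  category <- sample(names(config$category_mix), n_pay,
    replace = TRUE, prob = config$category_mix
  )

  # recipient strings rendered from the registry, Disclosure-style uppercase
  inst_name <- toupper(registry$name[practice_row])
  inst_loc <- toupper(paste0(
    registry$address[practice_row], " ", registry$postcode[practice_row]
  ))

  u <- stats::runif(n_pay)
  corruption <- ifelse(
    u < config$unmatchable_rate, "heavy",
    ifelse(u < config$unmatchable_rate + config$name_noise_rate, "light", "none")
  )
  li <- corruption == "light"
  if (any(li)) {
    noise_u <- stats::runif(sum(li))
    inst_name[li] <- light_corrupt(inst_name[li], noise_u)
    inst_loc[li] <- light_corrupt(inst_loc[li], stats::runif(sum(li)))
  }
  hv <- corruption == "heavy"
  if (any(hv)) {
    token <- sprintf("ZZ%06d", sample.int(999999L, sum(hv)))
    inst_name[hv] <- paste("HEALTH CENTRE", token)
    inst_loc[hv] <- paste(token, toupper(registry$region[practice_row][hv]))
  }

  # a subset of companies reports amounts VAT-inclusive
  inclusive_company <- companies[
    stats::runif(config$n_companies) < config$vat_inclusive_rate
  ]
  vat_basis <- ifelse(company %in% inclusive_company, "inclusive", "exclusive")
  amount <- ifelse(vat_basis == "inclusive",
    round_half_up(value * 1.2, 2), value
  )

  ord_ix <- sample.int(n_pay) # shuffle so file order carries no signal
  payments <- tibble::tibble(
    payment_id = seq_len(n_pay),
    company = company[ord_ix],
    institution_name = inst_name[ord_ix],
    institution_location = inst_loc[ord_ix],
    category = category[ord_ix],
    amount_gbp = amount[ord_ix],
    vat_basis = vat_basis[ord_ix]
  )
  truth <- tibble::tibble(
    payment_id = seq_len(n_pay),
    practice_code = registry$practice_code[practice_row][ord_ix],
    corruption = corruption[ord_ix]
  )
  structure(
    list(payments = payments, registry = registry, truth = truth, config = config),
    class = "synthetic_bundle"
  )
}

#' Generate a full synthetic bundle in one call
#'
#' @param config a [generator_config()].
#' @return a `synthetic_bundle` (see [generate_payments()]).
#' @export
simulate_bundle <- function(config = generator_config()) {
  generate_payments(generate_registry(config), config)
}

#' Write a synthetic bundle as three CSV files
#'
#' Writes `payments.csv` (columns `company`, `institution_name`,
#' `institution_location`, `category`, `amount_gbp`, `vat_basis`),
#' `registry.csv` and `truth.csv` into `dir`. Amounts are formatted with
#' exactly two decimals. Payment row order equals `payment_id`, so the
#' truth table remains joinable after a round trip through
#' [read_payments()].
#'
#' @param bundle a `synthetic_bundle`.
#' @param dir output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_bundle <- function(bundle, dir) {
  stopifnot(inherits(bundle, "synthetic_bundle"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  pay <- bundle$payments[, c(
    "company", "institution_name", "institution_location",
    "category", "amount_gbp", "vat_basis"
  )]
  pay$amount_gbp <- sprintf("%.2f", pay$amount_gbp)
  write.csv(pay, file.path(dir, "payments.csv"), row.names = FALSE)
  write.csv(bundle$registry, file.path(dir, "registry.csv"), row.names = FALSE)
  write.csv(bundle$truth, file.path(dir, "truth.csv"), row.names = FALSE)
  invisible(dir)
}
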