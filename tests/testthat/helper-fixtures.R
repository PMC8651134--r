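# compact generator settings: same structure as the default calibration but
# desk-sized, for tests that do not measure the calibration itself
small_config <- function(seed = 1, ...) {
  generator_config(
    n_companies = 8,
    n_practices = 400,
    dominant_donor = list(n_payments = 80, n_practices = 50),
    ordinary_donor_payments = list(meanlog = log(10), sdlog = 1, max = 80),
    seed = seed,
    ...
  )
}

small_bundle <- function(seed = 1, ...) simulate_bundle(small_config(seed, ...))

# minimal hand-built linked table: columns as produced by link_payments()$linked
tiny_linked <- function() {
  tibble::tibble(
    payment_id = 1:6,
    company = c("A", "A", "A", "B", "B", "C"),
    institution_name = "x",
    institution_location = "y",
    category = c(
      "donation_grant", "donation_grant", "event_contribution",
      "donation_grant", "service_consultancy", "event_contribution"
    ),
    amount_gbp = c(10, 20, 30, 100, 200, 50),
    vat_basis = "exclusive",
    practice_code = c("P1", "P1", "P2", "P1", "P3", "P2"),
    method = "exact_normalized",
    similarity = 1,
    matched_on = "institution_name"
  )
}

# company_network built directly from a weight matrix
make_net <- function(W, nodes = LETTERS[seq_len(nrow(W))]) {
  structure(
    list(
      weights = W, nodes = nodes,
      n_isolates = sum(rowSums(W) == 0),
      spec = threshold_spec(), stratum = NULL
    ),
    class = "company_network"
  )
}

# brute-force one-mode projection by explicit set intersection
brute_projection <- function(active_pairs) {
  nodes <- sort(unique(active_pairs$company))
  W <- matrix(0L, length(nodes), length(nodes), dimnames = list(nodes, nodes))
  for (i in seq_along(nodes)) {
    for (j in seq_along(nodes)) {
      if (i == j) next
      pi <- active_pairs$practice_code[active_pairs$company == nodes[i]]
      pj <- active_pairs$practice_code[active_pairs$company == nodes[j]]
      W[i, j] <- length(intersect(pi, pj))
    }
  }
  W
}
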