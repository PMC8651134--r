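pair_linked <- function(company, practice, amount) {
  tibble::tibble(
    payment_id = seq_along(company), company = company,
    institution_name = "x", institution_location = "y",
    category = "donation_grant", amount_gbp = amount,
    vat_basis = "exclusive", practice_code = practice,
    method = "exact_normalized", similarity = 1,
    matched_on = "institution_name"
  )
}

test_that("the three threshold bases activate pairs as specified", {
  lk <- pair_linked(c("A", "A"), c("p1", "p1"), c(50, 150))
  act <- function(spec) build_incidence(lk, spec)$active
  expect_true(act(threshold_spec("single_payment_value", 100)))
  expect_false(act(threshold_spec("single_payment_value", 200)))
  expect_true(act(threshold_spec("pair_total_value", 200)))
  expect_true(act(threshold_spec("pair_payment_count", 2)))
  expect_false(act(threshold_spec("pair_payment_count", 3)))
  # cutoff 0 keeps every paid pair
  expect_true(all(build_incidence(lk, threshold_spec("single_payment_value", 0))$active))
  expect_error(threshold_spec("single_payment_value", -1), class = "paynet_config_error")
})

test_that("projection counts shared practices; disjoint companies are isolates", {
  lk <- pair_linked(
    c("A", "A", "B", "B", "C"),
    c("p1", "p2", "p2", "p3", "p9"),
    rep(10, 5)
  )
  net <- project_network(build_incidence(lk, threshold_spec()))
  expect_identical(net$weights["A", "B"], 1L)
  expect_identical(net$weights["A", "C"], 0L)
  expect_identical(net$n_isolates, 1L)
  expect_identical(diag(net$weights), setNames(rep(0L, 3), c("A", "B", "C")))
  expect_identical(net$weights, t(net$weights))
})

test_that("projection equals brute-force set intersection on random incidences", {
  set.seed(20)
  for (i in 1:30) {
    n_c <- sample(2:6, 1)
    n_p <- sample(2:8, 1)
    pairs <- expand.grid(
      company = LETTERS[1:n_c],
      practice_code = sprintf("p%d", 1:n_p),
      stringsAsFactors = FALSE
    )
    pairs <- pairs[runif(nrow(pairs)) < 0.4, , drop = FALSE]
    if (nrow(pairs) == 0) next
    lk <- pair_linked(pairs$company, pairs$practice_code, rep(10, nrow(pairs)))
    net <- project_network(build_incidence(lk, threshold_spec()))
    ref <- brute_projection(pairs)
    expect_identical(unname(net$weights), unname(ref))
  }
})

test_that("projection equals exhaustive enumeration of all 3x3 incidences", {
  cells <- expand.grid(
    company = c("A", "B", "C"), practice_code = c("p1", "p2", "p3"),
    stringsAsFactors = FALSE
  )
  for (mask in 1:511) {
    on <- as.logical(bitwAnd(mask, 2^(0:8)))
    pairs <- cells[on, , drop = FALSE]
    lk <- pair_linked(pairs$company, pairs$practice_code, rep(10, nrow(pairs)))
    net <- project_network(build_incidence(lk, threshold_spec()))
    expect_identical(unname(net$weights), unname(brute_projection(pairs)))
  }
})

test_that("strength and degree follow the handshake identity", {
  star <- make_net(rbind(
    c(0, 1, 1, 1), c(1, 0, 0, 0), c(1, 0, 0, 0), c(1, 0, 0, 0)
  ))
  sd <- strength_and_degree(star)
  expect_equal(sd$strength, c(3, 1, 1, 1))
  expect_identical(sd$degree, c(3L, 1L, 1L, 1L))
  set.seed(21)
  for (i in 1:10) {
    n <- sample(3:7, 1)
    W <- matrix(sample(0:4, n * n, replace = TRUE), n)
    W[lower.tri(W)] <- t(W)[lower.tri(W)]
    diag(W) <- 0L
    net <- make_net(W)
    expect_equal(
      sum(strength_and_degree(net)$strength),
      2 * sum(W[upper.tri(W)])
    )
  }
})

test_that("valued density is the mean shared-practice count per pair", {
  all2 <- make_net(rbind(c(0, 2, 2), c(2, 0, 2), c(2, 2, 0)))
  expect_equal(valued_density(all2), 2)
  one <- make_net(rbind(c(0, 1, 0), c(1, 0, 0), c(0, 0, 0)))
  expect_equal(valued_density(one), 1 / 3)
  expect_equal(valued_density(one, ordered = TRUE), 1 / 6)
  expect_equal(valued_density(make_net(matrix(0L, 2, 2))), 0)
  expect_error(valued_density(make_net(matrix(0L, 1, 1))), class = "paynet_input_error")
})

test_that("centralization hits its stated extremes and the hand-computed path", {
  star <- make_net(rbind(
    c(0, 1, 1, 1), c(1, 0, 0, 0), c(1, 0, 0, 0), c(1, 0, 0, 0)
  ))
  expect_equal(centralization(star, "valued"), 1)
  expect_equal(centralization(star, "binary"), 1)
  complete <- make_net(matrix(3, 4, 4) - diag(3, 4))
  expect_equal(centralization(complete, "valued"), 0)
  path3 <- make_net(rbind(c(0, 2, 0), c(2, 0, 1), c(0, 1, 0)))
  expect_equal(centralization(path3, "valued"), 3 / 4)
  expect_equal(centralization(make_net(matrix(0L, 3, 3)), "valued"), 0)
  expect_error(centralization(make_net(matrix(0L, 2, 2))), class = "paynet_input_error")
})

test_that("valued centralization stays in [0,1] and matches binary on equal weights", {
  set.seed(22)
  for (i in 1:30) {
    n <- sample(3:8, 1)
    W <- matrix(sample(0:5, n * n, replace = TRUE), n)
    W[lower.tri(W)] <- t(W)[lower.tri(W)]
    diag(W) <- 0L
    net <- make_net(W)
    cv <- centralization(net, "valued")
    expect_gte(cv, 0)
    expect_lte(cv, 1)
    # all positive weights equal -> valued reduces to binary (Freeman)
    Wb <- (W > 0) * 4L
    netb <- make_net(Wb)
    expect_equal(
      centralization(netb, "valued"),
      centralization(netb, "binary")
    )
  }
})

test_that("binary statistics agree with igraph on random graphs", {
  set.seed(23)
  for (i in 1:10) {
    n <- sample(4:8, 1)
    W <- matrix(rbinom(n * n, 1, 0.4), n)
    W[lower.tri(W)] <- t(W)[lower.tri(W)]
    diag(W) <- 0L
    net <- make_net(W)
    g <- as_igraph(net)
    expect_equal(strength_and_degree(net)$degree, unname(igraph::degree(g)))
    expect_equal(
      centralization(net, "binary"),
      igraph::centr_degree(g, loops = FALSE)$centralization
    )
  }
})

test_that("raising the cutoff never increases weights, nodes or density", {
  b <- small_bundle(seed = 31)
  lk <- link_payments(normalize_vat(b$payments), b$registry)$linked
  cuts <- c(0, 100, 500, 1000, 2500)
  nets <- lapply(cuts, function(cut) {
    project_network(build_incidence(lk, threshold_spec("single_payment_value", cut)))
  })
  for (i in seq_along(cuts)[-1]) {
    lo <- nets[[i - 1]]
    hi <- nets[[i]]
    expect_lte(length(hi$nodes), length(lo$nodes))
    shared <- intersect(hi$nodes, lo$nodes)
    expect_true(all(hi$weights[shared, shared] <= lo$weights[shared, shared]))
    if (length(hi$nodes) >= 2 && length(lo$nodes) >= 2) {
      expect_lte(
        sum(hi$weights) / 2,
        sum(lo$weights) / 2
      )
    }
  }
})

test_that("stratified networks partition the unstratified active pairs", {
  b <- small_bundle(seed = 32)
  lk <- link_payments(normalize_vat(b$payments), b$registry)$linked
  prof <- profile_practices(lk, b$registry)
  strat <- stratified_networks(lk, prof, threshold_spec(), "size_quartile")
  expect_identical(sort(names(strat)), sort(as.character(1:4)))
  pair_key <- function(inc) {
    act <- inc[inc$active, ]
    sort(paste(act$company, act$practice_code))
  }
  full <- pair_key(build_incidence(lk, threshold_spec()))
  parts <- unlist(lapply(as.character(1:4), function(lab) {
    codes <- prof$practice_code[prof$size_quartile == as.integer(lab)]
    sub <- lk[lk$practice_code %in% codes, ]
    pair_key(build_incidence(sub, threshold_spec()))
  }))
  expect_identical(sort(parts), full)
})

test_that("degenerate strata are flagged rather than crashing", {
  lk <- pair_linked("A", "p1", 10)
  prof <- tibble::tibble(
    practice_code = "p1", region = "London", n_registered = 1000L,
    share_over_65 = 0.1, imd_decile = 5L, total_value_gbp = 10,
    n_payments = 1L, n_companies = 1L, size_quartile = 1L,
    elderly_quartile = 1L, imd_quartile = 1L
  )
  strat <- stratified_networks(lk, prof, threshold_spec(), "imd_quartile")
  expect_identical(names(strat), "1")
  expect_true(strat[["1"]]$stats$degenerate)
  expect_true(is.na(strat[["1"]]$stats$density))
})

test_that("the dominant donor has maximum strength under the default calibration", {
  for (s in 1:3) {
    b <- simulate_bundle(generator_config(seed = s))
    lk <- link_payments(normalize_vat(b$payments), b$registry)$linked
    net <- project_network(build_incidence(lk, threshold_spec()))
    sd <- strength_and_degree(net)
    expect_identical(
      sd$company[which.max(sd$strength)],
      "Company 01"
    )
  }
})

test_that("network exports round-trip edges and weights", {
  W <- rbind(c(0, 2, 0), c(2, 0, 1), c(0, 1, 0))
  net <- make_net(W)
  dir <- withr::local_tempdir()
  el_path <- file.path(dir, "edges.csv")
  write_network_edgelist(net, el_path)
  el <- read.csv(el_path)
  expect_identical(nrow(el), 2L)
  expect_identical(sum(el$shared_practices), 3L)
  gml <- file.path(dir, "net.graphml")
  write_network_graphml(net, gml)
  g <- igraph::read_graph(gml, format = "graphml")
  expect_equal(sort(igraph::E(g)$weight), c(1, 2))
})
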