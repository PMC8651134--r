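#' Threshold specification for network construction
#'
#' Defines which company-practice pairs count as "active" when building
#' the bipartite incidence: `single_payment_value` requires at least one
#' individual payment of at least `cutoff` GBP; `pair_total_value`
#' thresholds the company-to-practice total; `pair_payment_count`
#' thresholds the number of payments in the pair. `cutoff = 0` keeps every
#' paid pair.
#'
#' @param basis one of `"single_payment_value"`, `"pair_total_value"`,
#'   `"pair_payment_count"`.
#' @param cutoff nonnegative GBP value or count.
#' @return object of class `threshold_spec`.
#' @export
threshold_spec <- function(basis = c(
                             "single_payment_value", "pair_total_value",
                             "pair_payment_count"
                           ),
                           cutoff = 0) {
  basis <- match.arg(basis)
  if (!is.numeric(cutoff) || length(cutoff) != 1 || is.na(cutoff) || cutoff < 0) {
    abort("cutoff must be a nonnegative number", class = "paynet_config_error")
  }
  structure(list(basis = basis, cutoff = cutoff), class = "threshold_spec")
}

#' Build the thresholded company-practice incidence
#'
#' Aggregates linked payments into company-practice pairs with payment
#' counts and total values, and flags each pair active or not under the
#' threshold specification.
#'
#' @param linked nonempty linked payments tibble.
#' @param spec a [threshold_spec()].
#' @return object of class `bipartite_incidence`: tibble of pairs
#'   (`company`, `practice_code`, `n_payments`, `total_value_gbp`,
#'   `max_single_payment`, `active`) with the spec attached as an
#'   attribute.
#' @export
build_incidence <- function(linked, spec = threshold_spec()) {
  stopifnot(inherits(spec, "threshold_spec"))
  if (nrow(linked) == 0) abort("linked table is empty", class = "paynet_input_error")
  pairs <- linked |>
    dplyr::group_by(.data$company, .data$practice_code) |>
    dplyr::summarise(
      n_payments = dplyr::n(),
      total_value_gbp = sum(as_pence(.data$amount_gbp)) / 100,
      max_single_payment = max(.data$amount_gbp),
      .groups = "drop"
    )
  pairs$active <- switch(spec$basis,
    single_payment_value = pairs$max_single_payment >= spec$cutoff,
    pair_total_value = pairs$total_value_gbp >= spec$cutoff,
    pair_payment_count = pairs$n_payments >= spec$cutoff
  )
  structure(pairs, spec = spec, class = c("bipartite_incidence", class(pairs)))
}

#' Project the incidence onto a valued company network
#'
#' One-mode projection of the active company-practice pairs: the edge
#' weight between two companies is the number of practices both pay
#' (under the threshold). Nodes are the companies with at least one active
#' pair; companies sharing no practice with anyone are retained as
#' isolates and counted separately.
#'
#' @param incidence a [build_incidence()] result.
#' @param stratum optional stratum descriptor carried through to the result.
#' @return object of class `company_network`: list with `weights`
#'   (symmetric integer matrix, zero diagonal), `nodes`, `n_isolates`,
#'   `spec` and optional `stratum`.
#' @export
project_network <- function(incidence, stratum = NULL) {
  stopifnot(inherits(incidence, "bipartite_incidence"))
  act <- incidence[incidence$active, , drop = FALSE]
  nodes <- sort(unique(act$company))
  n <- length(nodes)
  if (n == 0) {
    W <- matrix(0L, 0, 0)
  } else {
    practices <- sort(unique(act$practice_code))
    A <- matrix(0L, n, length(practices), dimnames = list(nodes, practices))
    A[cbind(
      match(act$company, nodes),
      match(act$practice_code, practices)
    )] <- 1L
    W <- A %*% t(A)
    diag(W) <- 0L
    storage.mode(W) <- "integer"
  }
  structure(
    list(
      weights = W,
      nodes = nodes,
      n_isolates = if (n == 0) 0L else sum(rowSums(W) == 0),
      spec = attr(incidence, "spec"),
      stratum = stratum
    ),
    class = "company_network"
  )
}

#' Node strength and binary degree
#'
#' Strength is the sum of a node's edge weights (total shared-practice
#' count); degree is the number of positive-weight ties.
#'
#' @param net a `company_network`.
#' @return tibble: `company`, `strength`, `degree`.
#' @export
strength_and_degree <- function(net) {
  stopifnot(inherits(net, "company_network"))
  W <- net$weights
  tibble::tibble(
    company = net$nodes,
    strength = if (length(net$nodes)) as.numeric(rowSums(W)) else numeric(0),
    degree = if (length(net$nodes)) as.integer(rowSums(W > 0)) else integer(0)
  )
}

#' Valued density of a company network
#'
#' Mean shared-practice count per unordered company pair:
#' `sum_{i<j} w_ij / (n (n - 1) / 2)`. Can exceed 1 when pairs share
#' several practices. The ordered-pair (UCINET-style) convention divides by
#' `n (n - 1)` and gives exactly half this value.
#'
#' @param net a `company_network` with at least 2 nodes.
#' @param ordered use ordered pairs in the denominator (default FALSE).
#' @return nonnegative number.
#' @export
valued_density <- function(net, ordered = FALSE) {
  stopifnot(inherits(net, "company_network"))
  n <- length(net$nodes)
  if (n < 2) abort("density needs at least 2 nodes", class = "paynet_input_error")
  total <- sum(net$weights[upper.tri(net$weights)])
  pairs <- if (ordered) n * (n - 1) else n * (n - 1) / 2
  total / pairs
}

#' Degree/strength centralization of a company network
#'
#' Graph-level concentration of ties on one node, on a 0-1 scale:
#' the observed sum of (max - node) centrality differences divided by its
#' maximum attainable value. In `valued` mode centrality is node strength
#' and the denominator is `(n - 1) (n - 2) w_max` with `w_max` the largest
#' observed edge weight — this reduces exactly to Freeman degree
#' centralization when all weights are 0/1 and is attained by a
#' uniform-weight star. In `binary` mode the weight matrix is dichotomized
#' and Freeman degree centralization is returned. An all-zero network has
#' centralization 0 by convention.
#'
#' @param net a `company_network` with at least 3 nodes.
#' @param mode `"valued"` or `"binary"`.
#' @return fraction in `[0, 1]`.
#' @export
centralization <- function(net, mode = c("valued", "binary")) {
  mode <- match.arg(mode)
  stopifnot(inherits(net, "company_network"))
  n <- length(net$nodes)
  if (n < 3) abort("centralization needs at least 3 nodes", class = "paynet_input_error")
  W <- net$weights
  if (mode == "binary") W <- (W > 0) + 0L
  wmax <- max(W)
  if (wmax == 0) return(0)
  cent <- rowSums(W)
  sum(max(cent) - cent) / ((n - 1) * (n - 2) * wmax)
}

#' All graph-level and node-level network statistics
#'
#' @param net a `company_network`.
#' @return list with `node_stats` (tibble from [strength_and_degree()]),
#'   `n_nodes`, `n_isolates`, `density`, `centralization_valued`,
#'   `centralization_binary`, and `degenerate` (TRUE when the network is
#'   too small for the graph-level statistics, which are then `NA`).
#' @export
network_stats <- function(net) {
  stopifnot(inherits(net, "company_network"))
  n <- length(net$nodes)
  degenerate <- n < 2
  list(
    node_stats = strength_and_degree(net),
    n_nodes = n,
    n_isolates = net$n_isolates,
    density = if (n >= 2) valued_density(net) else NA_real_,
    centralization_valued = if (n >= 3) centralization(net, "valued") else NA_real_,
    centralization_binary = if (n >= 3) centralization(net, "binary") else NA_real_,
    degenerate = degenerate || n < 3
  )
}

#' Per-stratum company networks
#'
#' Filters practices to each stratum of a practice characteristic before
#' building the incidence, then projects and summarises one network per
#' stratum. Strata with fewer than two active companies are returned with
#' `NA` graph statistics and `degenerate = TRUE` rather than an error.
#'
#' @param linked linked payments tibble.
#' @param profiles practice profiles from [profile_practices()].
#' @param spec a [threshold_spec()].
#' @param grouping one of `"region"`, `"size_quartile"`,
#'   `"elderly_quartile"`, `"imd_quartile"`.
#' @return named list (one element per stratum label) of lists with
#'   `network` and `stats`.
#' @export
stratified_networks <- function(linked, profiles, spec = threshold_spec(),
                                grouping) {
  if (!grouping %in% grouping_choices()) {
    abort(
      paste0(
        "unknown grouping; use one of: ",
        paste(grouping_choices(), collapse = ", ")
      ),
      class = "paynet_input_error"
    )
  }
  strata <- as.character(profiles[[grouping]])
  labels <- sort(unique(strata))
  out <- lapply(labels, function(lab) {
    codes <- profiles$practice_code[strata == lab]
    sub <- linked[linked$practice_code %in% codes, , drop = FALSE]
    if (nrow(sub) == 0) {
      net <- structure(
        list(
          weights = matrix(0L, 0, 0), nodes = character(0),
          n_isolates = 0L, spec = spec, stratum = lab
        ),
        class = "company_network"
      )
    } else {
      net <- project_network(build_incidence(sub, spec), stratum = lab)
    }
    list(network = net, stats = network_stats(net))
  })
  names(out) <- labels
  out
}

#' Convert a company network to an igraph graph
#'
#' @param net a `company_network`.
#' @return an undirected weighted [igraph::graph] (isolates retained).
#' @export
as_igraph <- function(net) {
  stopifnot(inherits(net, "company_network"))
  igraph::graph_from_adjacency_matrix(
    net$weights,
    mode = "undirected", weighted = TRUE, diag = FALSE
  )
}

#' Export a company network
#'
#' `write_network_graphml()` writes GraphML (via igraph);
#' `write_network_edgelist()` writes a CSV edge list with columns
#' `company_a`, `company_b`, `shared_practices`.
#'
#' @param net a `company_network`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_network_graphml <- function(net, path) {
  igraph::write_graph(as_igraph(net), path, format = "graphml")
  invisible(path)
}

#' @rdname write_network_graphml
#' @export
write_network_edgelist <- function(net, path) {
  W <- net$weights
  idx <- which(upper.tri(W) & W > 0, arr.ind = TRUE)
  el <- data.frame(
    company_a = net$nodes[idx[, 1]],
    company_b = net$nodes[idx[, 2]],
    shared_practices = W[idx]
  )
  el <- el[order(el$company_a, el$company_b), , drop = FALSE]
  write.csv(el, path, row.names = FALSE)
  invisible(path)
}
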