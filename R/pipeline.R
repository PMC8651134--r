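#' End-to-end pipeline configuration
#'
#' A single structured configuration for the whole analysis: either a
#' simulation block (a [generator_config()]) or paths to payments and
#' registry files, plus the VAT policy, linkage threshold, network
#' threshold lists, stratification groupings and significance level.
#'
#' @param simulate a [generator_config()], or `NULL` when reading files.
#' @param payments_path,registry_path input CSVs (used when `simulate` is
#'   `NULL`).
#' @param vat a [vat_policy()].
#' @param fuzzy_threshold linkage acceptance threshold (default 0.90).
#' @param value_cutoffs GBP cutoffs for `single_payment_value` networks
#'   (default 0, 100, 1000, 2500).
#' @param count_cutoffs payment-count cutoffs for `pair_payment_count`
#'   networks (default 1, 2, 3).
#' @param groupings practice characteristics for stratified comparisons
#'   and stratified networks.
#' @param alpha significance threshold (default 0.05).
#' @param top_k donor count for the concentration share (default 10).
#' @param out_dir optional output directory; when set, [run_pipeline()]
#'   writes the full results bundle there.
#' @param seed optional integer; when given together with a simulate
#'   block it overrides the generator seed so that one seed drives all
#'   randomness.
#' @return object of class `pipeline_config`.
#' @export
pipeline_config <- function(simulate = generator_config(),
                            payments_path = NULL,
                            registry_path = NULL,
                            vat = vat_policy(),
                            fuzzy_threshold = 0.90,
                            value_cutoffs = c(0, 100, 1000, 2500),
                            count_cutoffs = c(1, 2, 3),
                            groupings = grouping_choices(),
                            alpha = 0.05,
                            top_k = 10,
                            out_dir = NULL,
                            seed = NULL) {
  if (is.null(simulate) && (is.null(payments_path) || is.null(registry_path))) {
    abort("either a simulate block or both input paths are required",
      class = "paynet_config_error"
    )
  }
  if (!is.null(simulate)) {
    stopifnot(inherits(simulate, "generator_config"))
    if (!is.null(seed)) {
      simulate$seed <- as.integer(seed)
    }
  }
  stopifnot(inherits(vat, "vat_policy"))
  if (!all(groupings %in% grouping_choices())) {
    abort("unknown grouping in `groupings`", class = "paynet_config_error")
  }
  structure(
    list(
      simulate = simulate,
      payments_path = payments_path,
      registry_path = registry_path,
      vat = vat,
      fuzzy_threshold = fuzzy_threshold,
      value_cutoffs = value_cutoffs,
      count_cutoffs = count_cutoffs,
      groupings = groupings,
      alpha = alpha,
      top_k = top_k,
      out_dir = out_dir,
      seed = seed
    ),
    class = "pipeline_config"
  )
}

#' Read a pipeline configuration from YAML
#'
#' Recognised top-level keys mirror the [pipeline_config()] arguments;
#' `simulate` holds [generator_config()] arguments, `vat` holds
#' [vat_policy()] arguments.
#'
#' @param path YAML file.
#' @return a `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  y <- yaml::read_yaml(path)
  simulate <- if (!is.null(y$simulate)) {
    args <- y$simulate
    for (nm in c("region_weights", "category_mix")) {
      if (!is.null(args[[nm]])) args[[nm]] <- unlist(args[[nm]])
    }
    do.call(generator_config, args)
  } else {
    NULL
  }
  vat <- if (!is.null(y$vat)) do.call(vat_policy, y$vat) else vat_policy()
  args <- y[setdiff(names(y), c("simulate", "vat"))]
  do.call(pipeline_config, c(list(simulate = simulate, vat = vat), args))
}

#' Run the full payments analysis pipeline
#'
#' Orchestrates simulate (or read), VAT normalisation, linkage,
#' enrichment, descriptives, stratified comparisons and network
#' construction from one configuration. Deterministic given the seed.
#'
#' @param config a [pipeline_config()].
#' @return object of class `paynet_results`: list with `payments`,
#'   `registry`, `linkage` (linked table + exclusion report), `profiles`,
#'   `summary_table`, `concentration` (company and practice),
#'   `top_share` (value and count shares of the top `top_k` donors),
#'   `category_breakdown`, `comparisons` (one tibble per grouping),
#'   `networks` (per threshold: network + stats), `stratified_networks`,
#'   and `manifest`. When `config$out_dir` is set the bundle is also
#'   written to disk (CSV tables, JSON summary, GraphML + edge lists).
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  if (!is.null(config$simulate)) {
    bundle <- simulate_bundle(config$simulate)
    payments <- bundle$payments
    registry <- bundle$registry
  } else {
    bundle <- NULL
    payments <- read_payments(config$payments_path)
    registry <- read_registry(config$registry_path)
  }
  payments <- normalize_vat(payments, config$vat)
  linkage <- link_payments(payments, registry, config$fuzzy_threshold)
  linked <- linkage$linked
  profiles <- profile_practices(linked, registry)

  conc_company <- concentration(linked, "company")
  conc_practice <- concentration(linked, "practice")
  k <- min(config$top_k, nrow(conc_company))
  top_share <- list(
    k = k,
    value = top_k_share(conc_company, k, "value"),
    count = top_k_share(conc_company, k, "count")
  )
  comparisons <- lapply(
    setNames(config$groupings, config$groupings),
    function(g) stratified_comparison(profiles, g, alpha = config$alpha)
  )

  nets <- list()
  for (cut in config$value_cutoffs) {
    spec <- threshold_spec("single_payment_value", cut)
    net <- project_network(build_incidence(linked, spec))
    nets[[paste0("value_", cut)]] <- list(network = net, stats = network_stats(net))
  }
  for (cut in config$count_cutoffs) {
    spec <- threshold_spec("pair_payment_count", cut)
    net <- project_network(build_incidence(linked, spec))
    nets[[paste0("count_", cut)]] <- list(network = net, stats = network_stats(net))
  }
  strat_nets <- lapply(
    setNames(config$groupings, config$groupings),
    function(g) stratified_networks(linked, profiles, threshold_spec(), g)
  )

  manifest <- list(
    package = "paynet",
    version = as.character(utils::packageVersion("paynet")),
    seed = if (!is.null(config$simulate)) config$simulate$seed else config$seed,
    config_hash = rlang::hash(config[setdiff(names(config), "out_dir")])
  )
  results <- structure(
    list(
      payments = payments,
      registry = registry,
      bundle = bundle,
      linkage = linkage,
      profiles = profiles,
      summary_table = summary_table(linked),
      concentration = list(company = conc_company, practice = conc_practice),
      top_share = top_share,
      category_breakdown = category_breakdown(linked),
      comparisons = comparisons,
      networks = nets,
      stratified_networks = strat_nets,
      manifest = manifest
    ),
    class = "paynet_results"
  )
  if (!is.null(config$out_dir)) write_results(results, config$out_dir)
  results
}

# flatten one network stats list to a data.frame row
stats_row <- function(name, st) {
  data.frame(
    network = name,
    n_nodes = st$n_nodes,
    n_isolates = st$n_isolates,
    density = st$density,
    centralization_valued = st$centralization_valued,
    centralization_binary = st$centralization_binary,
    degenerate = st$degenerate
  )
}

#' Write a results bundle to a directory
#'
#' Every number in the human-readable tables also appears in the
#' machine-readable `results.json`.
#'
#' @param results a `paynet_results` object.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_results <- function(results, dir) {
  stopifnot(inherits(results, "paynet_results"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  if (!is.null(results$bundle)) write_bundle(results$bundle, file.path(dir, "input"))

  wcsv <- function(x, nm) write.csv(x, file.path(dir, nm), row.names = FALSE)
  wcsv(results$linkage$matches, "linked_payments.csv")
  wcsv(results$profiles, "practice_profiles.csv")
  wcsv(results$summary_table, "summary_table.csv")
  wcsv(results$concentration$company, "concentration_company.csv")
  wcsv(results$concentration$practice, "concentration_practice.csv")
  wcsv(results$category_breakdown, "category_breakdown.csv")
  wcsv(dplyr::bind_rows(results$comparisons), "stratified_comparisons.csv")

  all_stats <- dplyr::bind_rows(
    lapply(names(results$networks), function(nm) {
      stats_row(nm, results$networks[[nm]]$stats)
    }),
    lapply(names(results$stratified_networks), function(g) {
      dplyr::bind_rows(lapply(
        names(results$stratified_networks[[g]]),
        function(lab) {
          stats_row(
            paste(g, lab, sep = ":"),
            results$stratified_networks[[g]][[lab]]$stats
          )
        }
      ))
    })
  )
  wcsv(all_stats, "network_stats.csv")
  for (nm in names(results$networks)) {
    net <- results$networks[[nm]]$network
    if (length(net$nodes) > 0) {
      write_network_edgelist(net, file.path(dir, paste0("network_", nm, ".csv")))
      write_network_graphml(net, file.path(dir, paste0("network_", nm, ".graphml")))
    }
  }

  json <- list(
    exclusion_report = unclass(results$linkage$report),
    top_share = results$top_share,
    category_breakdown = setNames(
      as.list(results$category_breakdown$share),
      results$category_breakdown$category
    ),
    summary_table = results$summary_table,
    comparisons = dplyr::bind_rows(results$comparisons),
    network_stats = all_stats,
    manifest = results$manifest
  )
  jsonlite::write_json(json, file.path(dir, "results.json"),
    auto_unbox = TRUE, digits = NA, pretty = TRUE
  )
  invisible(dir)
}
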