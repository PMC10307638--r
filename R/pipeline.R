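# End-to-end orchestration: placement treatment grids and the
# reconciliation -> ancestral-statistics chain, with provenance headers.

check_config <- function(config, allowed, required) {
  unknown <- setdiff(names(config), allowed)
  if (length(unknown))
    stop("unknown config key(s): ", paste(unknown, collapse = ", "))
  miss <- setdiff(required, names(config))
  if (length(miss))
    stop("missing config key(s): ", paste(miss, collapse = ", "))
  invisible(TRUE)
}

config_hash <- function(config) rlang::hash(config)

write_with_header <- function(df, path, hash, seed) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# config_hash=%s seed=%d", hash, as.integer(seed)),
             con)
  utils::write.table(df, con, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Run the placement treatment grid end to end
#'
#' @param config Named list with keys: `alignment` (AA20 alignment),
#'   `tree_for_rates` (guide tree), `backbone`, `query_taxa`,
#'   `candidates` (named clade list), `models` (per-alphabet list;
#'   defaults to Poisson models), `taxon_sets` (default no deletion),
#'   `recode_options` (default `c(FALSE, TRUE)`), `fsr_fractions`
#'   (default `c(0, 0.2)`), `seed` (required), `out_dir` (optional; grid
#'   TSV written there), `n_boot` (default 0), `optimize_edges`.
#' @return List with `grid` (the treatment-grid table), `hash`, `path`.
#' @export
run_placement_pipeline <- function(config) {
  check_config(config,
               allowed = c("alignment", "tree_for_rates", "backbone",
                           "query_taxa", "candidates", "models",
                           "taxon_sets", "recode_options", "fsr_fractions",
                           "seed", "out_dir", "n_boot", "optimize_edges"),
               required = c("alignment", "tree_for_rates", "backbone",
                            "query_taxa", "candidates", "seed"))
  models <- config$models %||%
    list(AA20 = substitution_model(20), SR4 = substitution_model(4))
  grid <- treatment_grid(
    aln_aa = config$alignment,
    tree_for_rates = config$tree_for_rates,
    models = models,
    taxon_sets = config$taxon_sets %||% list(none = character(0)),
    recode_options = config$recode_options %||% c(FALSE, TRUE),
    fsr_fractions = config$fsr_fractions %||% c(0, 0.2),
    backbone = config$backbone,
    query_taxa = config$query_taxa,
    candidates = config$candidates,
    optimize_edges = config$optimize_edges %||% "local",
    n_boot = config$n_boot %||% 0L,
    seed = config$seed)
  hash <- config_hash(config)
  path <- NULL
  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
    path <- file.path(config$out_dir, "placement_grid.tsv")
    write_with_header(grid, path, hash, config$seed)
  }
  list(grid = grid, hash = hash, path = path)
}

#' Run the reconciliation -> ancestral statistics chain
#'
#' Singletons are scored as originations at their leaf; families above
#' the size cap are skipped with a warning; per-family reconciliations
#' are sampled and aggregated into copy tables, ancestor profiles and a
#' group report.
#'
#' @param config Named list with keys: `families` (list of
#'   [gene_family()]), `stree`, `rates` (a [dtl_rates()]; or omit and set
#'   `estimate_rates = TRUE` for a pooled ML fit), `estimate_rates`,
#'   `groups` (named node-label -> group vector, optional),
#'   `reference_group`, `n_samples` (default 100), `seed` (required),
#'   `thresholds` (list; defaults `theta_event = 0.3`,
#'   `theta_present = 0.3`, `theta_maybe = 0.1`), `size_cap` (default
#'   2000), `out_dir`.
#' @return List with `reconciliations`, `aggregate`, `profiles`,
#'   `report` (NULL without groups), `skipped`, `hash`.
#' @export
run_ancestral_pipeline <- function(config) {
  check_config(config,
               allowed = c("families", "stree", "rates", "estimate_rates",
                           "groups", "reference_group", "n_samples",
                           "seed", "thresholds", "size_cap", "out_dir"),
               required = c("families", "stree", "seed"))
  th <- config$thresholds %||% list()
  theta_event <- th$theta_event %||% 0.3
  theta_present <- th$theta_present %||% 0.3
  size_cap <- config$size_cap %||% 2000L
  n_samples <- config$n_samples %||% 100L
  stree <- config$stree
  families <- config$families
  big <- vapply(families, `[[`, numeric(1L), "size") > size_cap
  if (any(big)) {
    warning(sum(big), " family(ies) above the size cap (", size_cap,
            ") skipped: ",
            paste(vapply(families[big], `[[`, "", "id"), collapse = ", "))
    families <- families[!big]
  }
  rates <- config$rates
  if (is.null(rates)) {
    if (!isTRUE(config$estimate_rates))
      stop("missing config key(s): rates (or set estimate_rates = TRUE)")
    multi <- families[vapply(families, `[[`, numeric(1L), "size") > 1L]
    rates <- estimate_rates(multi, stree)
  }
  recons <- vector("list", length(families))
  for (i in seq_along(families)) {
    fam <- families[[i]]
    recons[[i]] <- if (fam$size == 1L) singleton_origination(fam, stree)
    else sample_reconciliations(fam, stree, rates, n = n_samples,
                                seed = config$seed + i)
  }
  agg <- aggregate_reconciliations(recons, stree)
  profiles <- ancestor_profiles(recons, stree,
                                theta_present = theta_present)
  report <- NULL
  if (!is.null(config$groups)) {
    if (is.null(config$reference_group))
      stop("missing config key(s): reference_group")
    report <- group_report(profiles, config$groups, config$reference_group)
  }
  hash <- config_hash(config[setdiff(names(config), "out_dir")])
  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
    seed <- config$seed
    write_with_header(as.data.frame(agg$copies_corrected) |>
                        (\(d) cbind(family = rownames(agg$copies_corrected),
                                    d))(),
                      file.path(config$out_dir, "copies_corrected.tsv"),
                      hash, seed)
    write_with_header(agg$events,
                      file.path(config$out_dir, "branch_events.tsv"),
                      hash, seed)
    write_with_header(profiles,
                      file.path(config$out_dir, "ancestor_profiles.tsv"),
                      hash, seed)
    if (!is.null(report))
      write_with_header(report,
                        file.path(config$out_dir, "group_report.tsv"),
                        hash, seed)
    ev <- do.call(rbind, lapply(recons, function(r)
      cbind(family = r$family_id,
            filter_events(r$events, theta_event))))
    write_with_header(ev, file.path(config$out_dir, "events.tsv"),
                      hash, seed)
  }
  list(reconciliations = recons, aggregate = agg, profiles = profiles,
       report = report, rates = rates,
       skipped = if (any(big)) vapply(config$families[big], `[[`, "", "id")
                 else character(0),
       hash = hash)
}
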