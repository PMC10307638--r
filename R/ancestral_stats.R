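# Per-ancestor proteome sizes, normalized event rates, and group
# comparisons against a reference set of ancestors.

#' Aggregate reconciliations into per-branch copy and event tables
#'
#' @param recons List of `phd_reconciliation` objects (one per family).
#' @param stree The shared [species_tree()].
#' @return List with `copies_raw` and `copies_corrected`
#'   (family x branch matrices), and `events`: per-branch expected counts
#'   (means over samples, summed over families) for duplications, losses,
#'   transfers and originations.
#' @export
aggregate_reconciliations <- function(recons, stree) {
  B <- stree$n_branches
  nf <- length(recons)
  raw <- corrected <- matrix(0, nf, B)
  ev <- matrix(0, B, 4L,
               dimnames = list(NULL, c("duplication", "loss", "transfer",
                                       "origination")))
  type_col <- c(D = "duplication", L = "loss", T = "transfer",
                O = "origination")
  for (i in seq_len(nf)) {
    r <- recons[[i]]
    raw[i, ] <- r$copies
    corrected[i, ] <- r$copies / r$observability
    cnt <- matrix(0, B, 4L)
    for (s in r$samples) {
      keep <- s$type %in% names(type_col)
      if (!any(keep)) next
      tb <- table(factor(type_col[s$type[keep]], levels = colnames(ev)),
                  factor(s$branch[keep], levels = seq_len(B)))
      cnt <- cnt + matrix(t(tb), nrow = B)
    }
    ev <- ev + cnt / length(r$samples)
  }
  rownames(raw) <- rownames(corrected) <-
    vapply(recons, `[[`, "", "family_id")
  list(copies_raw = raw, copies_corrected = corrected,
       events = data.frame(branch = seq_len(B), label = stree$labels,
                           ev, stringsAsFactors = FALSE))
}

#' Proteome size at a node: families whose copy number clears the
#' presence threshold
#'
#' @param node Branch index (or label) of the ancestral node.
#' @param copy_table Family x branch matrix of (corrected) copy numbers.
#' @param stree Species tree (needed when `node` is a label).
#' @param theta_present Presence threshold; a family counts if its copy
#'   number is strictly above it (default 0.3).
#' @export
proteome_size <- function(node, copy_table, stree = NULL,
                          theta_present = 0.3) {
  b <- resolve_branch(node, copy_table, stree)
  sum(copy_table[, b] > theta_present)
}

resolve_branch <- function(node, copy_table, stree) {
  if (is.character(node)) {
    if (is.null(stree)) stop("species tree needed to resolve node labels")
    b <- match(node, stree$labels)
    if (is.na(b)) stop("unknown node: ", node)
    return(b)
  }
  if (node < 1 || node > ncol(copy_table)) stop("unknown node: ", node)
  as.integer(node)
}

#' Normalized event rates for one ancestral node
#'
#' Each event-class total at the node is divided by the node's proteome
#' size.
#'
#' @param node Branch index or label.
#' @param event_table Per-branch event table from
#'   [aggregate_reconciliations()].
#' @param size Proteome size at the node (> 0).
#' @return One-row `data.frame`: node, proteome size and one normalized
#'   rate per event class.
#' @export
normalized_event_rates <- function(node, event_table, size) {
  if (size <= 0) stop("proteome size must be positive to normalize rates")
  b <- if (is.character(node)) match(node, event_table$label)
       else as.integer(node)
  if (is.na(b) || b < 1 || b > nrow(event_table))
    stop("unknown node: ", node)
  classes <- setdiff(colnames(event_table), c("branch", "label"))
  out <- data.frame(node = event_table$label[b], proteome_size = size)
  for (cl in classes) out[[cl]] <- event_table[[cl]][b] / size
  out
}

#' Build ancestor profiles (size + normalized rates) for internal nodes
#'
#' @param recons List of reconciliations.
#' @param stree Species tree.
#' @param theta_present Presence threshold for the proteome size.
#' @export
ancestor_profiles <- function(recons, stree, theta_present = 0.3) {
  agg <- aggregate_reconciliations(recons, stree)
  nodes <- which(!stree$is_leaf)
  rows <- lapply(nodes, function(b) {
    size <- proteome_size(b, agg$copies_corrected, stree, theta_present)
    if (size == 0) return(NULL)
    cbind(branch = b, normalized_event_rates(b, agg$events, size))
  })
  do.call(rbind, rows)
}

#' One-sample Wilcoxon signed-rank test against a reference value
#'
#' Two-sided test of per-ancestor rates against a scalar reference
#' (typically the median of the reference ancestors).  Exact null
#' distribution (by convolution over signed midranks) for n <= 25, normal
#' approximation with continuity and tie correction beyond.  Values tied
#' with the reference are dropped; no multiple-testing correction is
#' applied.
#'
#' @param values Numeric vector of per-ancestor rates.
#' @param reference Scalar reference value.
#' @param exact_max Largest n for which the exact distribution is used.
#' @return List with `statistic` (W+, rank sum of positive differences),
#'   `n` (after dropping ties) and `p.value`.
#' @export
wilcoxon_vs_reference <- function(values, reference, exact_max = 25L) {
  d <- values - reference
  d <- d[d != 0]
  n <- length(d)
  if (n < 3L) stop("insufficient ancestors: n = ", n,
                   " after dropping ties with the reference")
  r <- rank(abs(d))
  W <- sum(r[d > 0])
  if (n <= exact_max) {
    R <- as.integer(round(2 * r))          # doubled midranks are integers
    tot <- sum(R)
    f <- numeric(tot + 1L); f[1L] <- 1     # counts of doubled-W values
    for (x in R)
      f <- f + c(rep(0, x), f[seq_len(tot + 1L - x)])
    w2 <- as.integer(round(2 * W))
    ple <- sum(f[seq_len(w2 + 1L)]) / 2^n
    pge <- sum(f[(w2 + 1L):(tot + 1L)]) / 2^n
    p <- min(1, 2 * min(ple, pge))
  } else {
    mu <- n * (n + 1) / 4
    tie_tab <- table(r)
    sigma2 <- n * (n + 1) * (2 * n + 1) / 24 -
      sum(tie_tab^3 - tie_tab) / 48
    z <- W - mu
    z <- (z - sign(z) * 0.5) / sqrt(sigma2)
    p <- min(1, 2 * min(stats::pnorm(z), stats::pnorm(z, lower.tail = FALSE)))
  }
  list(statistic = W, n = n, p.value = p)
}

significance_stars <- function(p) {
  ifelse(p <= 0.001, "***", ifelse(p <= 0.01, "**",
                                   ifelse(p <= 0.05, "*", "")))
}

#' Group report: medians, IQRs and Wilcoxon p-values per ancestor group
#'
#' For every non-reference group and event class, tests the group's
#' per-ancestor normalized rates against the median rate of the
#' reference-group ancestors (two-sided one-sample Wilcoxon, no
#' multiple-testing correction) and annotates significance stars
#' (p <= 0.05 `*`, <= 0.01 `**`, <= 0.001 `***`).
#'
#' @param profiles Profile table from [ancestor_profiles()].
#' @param groups Named character vector: node label -> group name.
#' @param reference_group Name of the reference group.
#' @param event_classes Event-rate columns to compare.
#' @return `data.frame` with one row per (group, event class).
#' @export
group_report <- function(profiles, groups, reference_group,
                         event_classes = c("duplication", "loss",
                                           "origination")) {
  grp <- groups[profiles$node]
  if (!any(grp == reference_group, na.rm = TRUE))
    stop("reference group '", reference_group, "' matches no ancestors")
  rows <- list()
  for (g in setdiff(unique(stats::na.omit(grp)), reference_group)) {
    for (cl in event_classes) {
      vals <- profiles[[cl]][which(grp == g)]
      ref <- stats::median(profiles[[cl]][which(grp == reference_group)])
      res <- tryCatch(wilcoxon_vs_reference(vals, ref),
                      error = function(e) list(p.value = NA_real_,
                                               n = length(vals)))
      rows[[length(rows) + 1L]] <- data.frame(
        group = g, event_class = cl, n = res$n,
        median = stats::median(vals),
        iqr = stats::IQR(vals), reference_median = ref,
        p.value = res$p.value,
        stars = if (is.na(res$p.value)) ""
                else significance_stars(res$p.value),
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
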