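# Constrained placement of a query clade on a backbone tree, and the
# treatment grid crossing taxon sampling x recoding x fast-site removal.

#' Identify a backbone edge by the clade below it
#'
#' Returns the index (row of `tree$edge`) of the edge whose bipartition
#' separates exactly `taxa` from the rest of the tips.
#'
#' @param tree Unrooted or rooted `phylo`.
#' @param taxa Character vector of tip labels on one side of the edge.
#' @export
edge_by_clade <- function(tree, taxa) {
  tips <- tree$tip.label
  if (!all(taxa %in% tips))
    stop("unknown tips: ", paste(setdiff(taxa, tips), collapse = ", "))
  target <- sort(match(taxa, tips))
  below <- tips_below(tree)
  for (e in seq_len(nrow(tree$edge))) {
    side <- below[[tree$edge[e, 2L]]]
    if (identical(sort(side), target) ||
        identical(sort(setdiff(seq_along(tips), side)), target))
      return(e)
  }
  stop("no edge separates {", paste(taxa, collapse = ","), "} in the tree")
}

# tip indices below each node (index = node id)
tips_below <- function(tree) {
  nt <- length(tree$tip.label)
  nn <- nt + tree$Nnode
  below <- vector("list", nn)
  for (i in seq_len(nt)) below[[i]] <- i
  edge <- stats::reorder(tree, "postorder")$edge
  for (e in seq_len(nrow(edge)))
    below[[edge[e, 1L]]] <- c(below[[edge[e, 1L]]], below[[edge[e, 2L]]])
  below
}

# Deterministically rooted query subtree (topology from NJ on LogDet
# distances of the query block; rooted on the edge incident to the
# alphabetically first query taxon).
query_subtree <- function(aln, query_taxa) {
  if (length(query_taxa) == 1L) {
    tr <- list(edge = matrix(c(2L, 1L), 1L), tip.label = query_taxa,
               edge.length = 0.1, Nnode = 1L)
    class(tr) <- "phylo"
    return(tr)
  }
  sub <- subset_taxa(aln, setdiff(aln$taxa, query_taxa))
  d <- logdet_distance(sub)
  d[is.na(d)] <- max(d, na.rm = TRUE) * 2
  tr <- nj_tree(d)
  if (length(query_taxa) > 2L)
    tr <- ape::root(tr, outgroup = sort(query_taxa)[1L], resolve.root = TRUE)
  tr
}

#' Rank candidate attachment edges for a query clade
#'
#' The query clade (held monophyletic; internal topology fixed from an NJ
#' subtree on LogDet distances) is attached in turn to each candidate edge
#' of the backbone; branch lengths are re-optimized by per-branch Brent
#' coordinate ascent and candidates are ranked by log-likelihood.
#'
#' @param aln Alignment containing both backbone and query taxa.
#' @param backbone `phylo` tree over the non-query taxa, with branch
#'   lengths.
#' @param query_taxa Tips to place (present in `aln`, absent from
#'   `backbone`).
#' @param candidates Edge indices into `backbone$edge`, or a *named* list
#'   of tip-label vectors identifying edges via [edge_by_clade()].
#' @param model A [substitution_model()] matching the alignment alphabet.
#' @param optimize_edges `"local"` (default) re-optimizes the attachment
#'   edges and the query subtree; `"all"` re-optimizes every branch.
#' @param tol Log-likelihood convergence tolerance between sweeps.
#' @param max_sweeps Maximum coordinate-ascent sweeps.
#' @param n_boot Optional bootstrap replicates for placement support
#'   (0 = none); replicates whose two best candidates differ by less than
#'   1e-6 log-likelihood count for neither.
#' @param seed Seed for the bootstrap resampling.
#' @return `data.frame` (class `phd_placement`) with one row per
#'   candidate: `candidate`, `edge`, `loglik`, `support`, sorted by
#'   decreasing log-likelihood.
#' @export
constrained_placement <- function(aln, backbone, query_taxa, candidates,
                                  model, optimize_edges = c("local", "all"),
                                  tol = 1e-4, max_sweeps = 50L,
                                  n_boot = 0L, seed = 1L) {
  optimize_edges <- match.arg(optimize_edges)
  if (!all(query_taxa %in% aln$taxa))
    stop("query taxa missing from alignment")
  if (any(query_taxa %in% backbone$tip.label))
    stop("query taxa must be absent from the backbone")
  cand <- resolve_candidates(backbone, candidates)
  if (length(cand$edge) == 0L) stop("empty candidate set")
  qsub <- query_subtree(aln, query_taxa)
  ll <- vapply(cand$edge, function(e)
    placement_loglik(aln, backbone, qsub, e, model, optimize_edges,
                     tol, max_sweeps)$loglik, numeric(1L))
  res <- data.frame(candidate = cand$name, edge = cand$edge, loglik = ll,
                    support = NA_real_, stringsAsFactors = FALSE)
  if (n_boot > 0L) {
    wins <- stats::setNames(numeric(length(cand$edge)), cand$name)
    reps <- with_seed(seed, lapply(seq_len(n_boot), function(r)
      sample(seq_len(aln$n_cols), aln$n_cols, replace = TRUE)))
    for (cols in reps) {
      sub <- subset_columns(aln, cols - 1L)
      llb <- vapply(cand$edge, function(e)
        placement_loglik(sub, backbone, qsub, e, model, optimize_edges,
                         tol, max_sweeps)$loglik, numeric(1L))
      srt <- sort(llb, decreasing = TRUE)
      if (length(llb) == 1L || srt[1L] - srt[2L] >= 1e-6)
        wins[which.max(llb)] <- wins[which.max(llb)] + 1
    }
    res$support <- as.numeric(wins / n_boot)
  }
  res <- res[order(-res$loglik), ]
  rownames(res) <- NULL
  class(res) <- c("phd_placement", "data.frame")
  res
}

resolve_candidates <- function(backbone, candidates) {
  if (is.list(candidates)) {
    if (is.null(names(candidates)) || any(!nzchar(names(candidates))))
      stop("candidate clades must be named")
    edges <- vapply(candidates, function(cl)
      edge_by_clade(backbone, intersect(cl, backbone$tip.label)),
      integer(1L))
    list(name = names(candidates), edge = unname(edges))
  } else {
    list(name = sprintf("edge%d", as.integer(candidates)),
         edge = as.integer(candidates))
  }
}

# Attach the query subtree to backbone edge `e`, optimize branch lengths,
# return log-likelihood and the fitted tree.
placement_loglik <- function(aln, backbone, qsub, e, model,
                             optimize_edges = "local", tol = 1e-4,
                             max_sweeps = 50L) {
  qsub$root.edge <- 0.1
  child <- backbone$edge[e, 2L]
  pos <- max(backbone$edge.length[e] / 2, 1e-8)
  full <- ape::bind.tree(backbone, qsub, where = child, position = pos)
  full$edge.length[full$edge.length < 1e-8] <- 1e-8
  prep <- lik_prep(aln, full, model)
  n_edge <- nrow(prep$tree$edge)
  idx <- if (optimize_edges == "all") seq_len(n_edge)
         else local_edge_set(prep$tree, qsub$tip.label)
  len <- prep$tree$edge.length
  obj <- function(lv) sum(lik_pattern_loglik(prep, lv, alpha = model$alpha,
                                             k_cat = model$k_cat) * prep$w)
  # one global branch-length scale first: input lengths may sit on a
  # different substitution scale than the data (e.g. after recoding)
  sc <- stats::optimize(function(s) -obj(len * s), interval = c(0.05, 20),
                        tol = 1e-3)
  len <- len * sc$minimum
  cur <- obj(len)
  prev <- -Inf
  for (sweep in seq_len(max_sweeps)) {
    for (i in idx) {
      o <- stats::optimize(function(x) {
        len2 <- len; len2[i] <- x; -obj(len2)
      }, interval = c(1e-8, 10), tol = 1e-4)
      if (-o$objective > cur) { len[i] <- o$minimum; cur <- -o$objective }
    }
    if (cur - prev < tol) break
    prev <- cur
  }
  list(loglik = cur, tree = { prep$tree$edge.length <- len; prep$tree })
}

# Edges of the query subtree, its stem, and the edges around the
# attachment node (EPA-style local optimization set).  `tree` is in
# postorder; edges are identified by their child node.
local_edge_set <- function(tree, query_tips) {
  edge <- tree$edge
  nn <- max(edge)
  qt <- match(query_tips, tree$tip.label)
  mrca <- if (length(qt) == 1L) qt
          else ape::getMRCA(tree, tree$tip.label[qt])
  insub <- logical(nn)
  insub[mrca] <- TRUE
  # reverse postorder puts parents before children
  for (e in rev(seq_len(nrow(edge))))
    if (insub[edge[e, 1L]]) insub[edge[e, 2L]] <- TRUE
  parent <- integer(nn)
  parent[edge[, 2L]] <- edge[, 1L]
  att <- parent[mrca]
  childset <- which(insub)
  if (att > 0L)
    childset <- c(childset, att, edge[edge[, 1L] == att, 2L])
  sort(which(edge[, 2L] %in% childset))
}

#' Treatment grid: taxon sampling x recoding x fast-site removal
#'
#' Runs [constrained_placement()] for every combination of taxon-deletion
#' set, recoding option and fast-site-removal fraction, recomputing site
#' rates on the (taxon-subsetted) amino-acid alignment before removal and
#' recoding, and reports the winning candidate per cell.
#'
#' @param aln_aa Full `AA20` alignment (query + backbone taxa).
#' @param tree_for_rates Guide tree with branch lengths for site-rate
#'   estimation (tips pruned automatically per taxon set).
#' @param models Named list of models keyed by alphabet tag, e.g.
#'   `list(AA20 = ..., SR4 = ...)`.
#' @param taxon_sets Named list of taxon sets to drop (use
#'   `list(none = character(0))` for no deletion).
#' @param recode_options Logical vector, e.g. `c(FALSE, TRUE)`.
#' @param fsr_fractions Numeric vector of removal fractions (0 = none).
#' @param backbone Backbone tree over all non-query taxa.
#' @param query_taxa Taxa to place.
#' @param candidates Named list of candidate clades (tip-label vectors).
#' @param ... Passed to [constrained_placement()].
#' @return `data.frame` with one row per grid cell: `taxon_set`,
#'   `recoded`, `fraction`, `winner`, `loglik`, `margin` (log-likelihood
#'   lead over the runner-up), `support`.
#' @export
treatment_grid <- function(aln_aa, tree_for_rates, models, taxon_sets,
                           recode_options, fsr_fractions, backbone,
                           query_taxa, candidates, ...) {
  stopifnot(aln_aa$alphabet == "AA20")
  rows <- list()
  for (ts in names(taxon_sets)) {
    drop <- setdiff(taxon_sets[[ts]], query_taxa)
    aln_ts <- if (length(drop)) subset_taxa(aln_aa, drop) else aln_aa
    guide <- if (length(intersect(drop, tree_for_rates$tip.label)))
      ape::drop.tip(tree_for_rates, intersect(drop, tree_for_rates$tip.label))
    else tree_for_rates
    bb <- if (length(intersect(drop, backbone$tip.label)))
      ape::drop.tip(backbone, intersect(drop, backbone$tip.label))
    else backbone
    alpha_ts <- NULL
    for (f in fsr_fractions) for (rc in recode_options) {
      if (f > 0 && is.null(alpha_ts))
        alpha_ts <- estimate_alpha(aln_ts, guide, models$AA20)
      treated <- treat_alignment(aln_ts, guide, models$AA20, f,
                                 recode_scheme = if (rc) sr4_scheme(),
                                 alpha = alpha_ts)
      model <- models[[treated$alphabet]]
      if (is.null(model))
        stop("no model supplied for alphabet ", treated$alphabet)
      cand_ts <- lapply(candidates, function(cl) setdiff(cl, drop))
      res <- constrained_placement(treated, bb, query_taxa, cand_ts,
                                   model, ...)
      rows[[length(rows) + 1L]] <- data.frame(
        taxon_set = ts, recoded = rc, fraction = f,
        winner = res$candidate[1L], loglik = res$loglik[1L],
        margin = if (nrow(res) > 1L) res$loglik[1L] - res$loglik[2L]
                 else NA_real_,
        support = res$support[1L], stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}
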