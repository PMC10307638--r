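# Conditional clade probabilities (CCP) from a gene-tree sample, enabling
# amalgamated reconciliation likelihoods over topologies.

#' Conditional clade probabilities from a sample of rooted trees
#'
#' Counts observed clades and, within each non-leaf clade, its observed
#' child splits, across a sample of rooted binary trees with identical
#' leaf sets.
#'
#' @param trees List of rooted binary `phylo` objects (e.g. a bootstrap or
#'   posterior sample) sharing one leaf set.
#' @return A `phd_ccp` object: `leaves` (sorted labels), `n_trees`,
#'   `clade_freq` (named vector, keys are comma-joined leaf indices),
#'   `splits` (per clade, list of `(k1, k2, w)` with conditional
#'   frequencies `w` summing to 1).
#' @export
ccp_from_trees <- function(trees) {
  if (inherits(trees, "phylo")) trees <- list(trees)
  if (length(trees) < 1L) stop("need at least one tree")
  leaves <- sort(trees[[1L]]$tip.label)
  for (tr in trees) {
    if (!identical(sort(tr$tip.label), leaves))
      stop("inconsistent leaf sets across the tree sample")
    if (!ape::is.rooted(tr) || !ape::is.binary(tr))
      stop("CCP construction expects rooted binary trees")
  }
  clade_count <- new.env(parent = emptyenv())
  split_count <- new.env(parent = emptyenv())
  bump <- function(env, key) assign(key, (env[[key]] %||% 0) + 1, envir = env)
  for (tr in trees) {
    idx <- match(tr$tip.label, leaves)
    ls <- node_leafsets(tr)
    ls <- lapply(ls, function(s) sort(idx[s]))
    nt <- length(tr$tip.label)
    edge <- stats::reorder(tr, "postorder")$edge
    kids <- split(edge[, 2L], edge[, 1L])
    for (v in seq_along(ls)) {
      key <- paste(ls[[v]], collapse = ",")
      bump(clade_count, key)
      if (v > nt) {
        ch <- kids[[as.character(v)]]
        k1 <- paste(ls[[ch[1L]]], collapse = ",")
        k2 <- paste(ls[[ch[2L]]], collapse = ",")
        if (k2 < k1) { tmp <- k1; k1 <- k2; k2 <- tmp }
        bump(split_count, paste(key, k1, k2, sep = "|"))
      }
    }
  }
  n <- length(trees)
  clade_freq <- unlist(as.list(clade_count)) / n
  splits <- list()
  for (sk in ls(split_count)) {
    parts <- strsplit(sk, "|", fixed = TRUE)[[1L]]
    w <- split_count[[sk]] / clade_count[[parts[1L]]]
    splits[[parts[1L]]] <- c(splits[[parts[1L]]],
                             list(list(k1 = parts[2L], k2 = parts[3L],
                                       w = w)))
  }
  structure(list(leaves = leaves, n_trees = n, clade_freq = clade_freq,
                 splits = splits),
            class = "phd_ccp")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Convert a CCP set into the clade graph consumed by the reconciliation
# DP; `sp_map` gives the species-branch index of each CCP leaf.
ccp_to_graph <- function(ccp, sp_map) {
  cg <- new_clade_graph(sp_map)
  keys <- names(ccp$clade_freq)
  sizes <- lengths(strsplit(keys, ",", fixed = TRUE))
  ids <- new.env(parent = emptyenv())
  for (key in keys[order(sizes)]) {
    idx <- as.integer(strsplit(key, ",", fixed = TRUE)[[1L]])
    ids[[key]] <- cg_add_clade(cg, idx)
    for (s in ccp$splits[[key]])
      cg_add_split(cg, ids[[key]], ids[[s$k1]], ids[[s$k2]], s$w)
  }
  cg$top <- ids[[paste(seq_along(ccp$leaves), collapse = ",")]]
  cg
}
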