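# Undated duplication-transfer-loss (DTL) reconciliation with a
# genome-incompleteness (missing-fraction) correction.
#
# Event probabilities on every species branch derive from the rates
# (delta, tau, lambda) through Z = 1 + delta + tau + lambda:
#   P_S = 1/Z (speciation or leaf arrival), P_D = delta/Z,
#   P_T = tau/Z (copy sent to a uniformly chosen other branch),
#   P_L = lambda/Z.
# Branches are indexed by the node below them (ape ids), so the root
# branch is included and indices are stable under serialization.

#' Indexed species tree with per-leaf missing fractions
#'
#' @param tree Rooted binary `phylo`.
#' @param completeness Optional named vector of genome completeness in
#'   (0, 1] per tip; the missing fraction is `1 - completeness`.
#' @param missing Alternatively, named per-tip missing fractions in
#'   `[0, 1)` directly.  Unlisted tips get 0.
#' @return A `phd_species_tree`: `tree`, `n_leaves`, `n_branches`
#'   (`2n - 1`, root branch included), `children` (two-column matrix per
#'   branch, `NA` rows for leaves), `is_leaf`, `labels` (branch labels:
#'   tip labels for leaves, node labels or `node<i>` for internals), `m`
#'   (missing fraction per branch, 0 on internal branches), `root`.
#' @export
species_tree <- function(tree, completeness = NULL, missing = NULL) {
  if (!ape::is.rooted(tree) || !ape::is.binary(tree))
    stop("species tree must be rooted and binary")
  nt <- length(tree$tip.label)
  B <- 2L * nt - 1L
  children <- matrix(NA_integer_, B, 2L)
  for (e in seq_len(nrow(tree$edge))) {
    p <- tree$edge[e, 1L]
    slot <- if (is.na(children[p, 1L])) 1L else 2L
    children[p, slot] <- tree$edge[e, 2L]
  }
  is_leaf <- seq_len(B) <= nt
  if (!is.null(completeness)) {
    if (any(completeness <= 0 | completeness > 1))
      stop("completeness values must lie in (0, 1]")
    missing <- 1 - completeness
  }
  m <- stats::setNames(rep(0, B), NULL)
  if (!is.null(missing)) {
    if (any(missing < 0 | missing >= 1))
      stop("missing fractions must lie in [0, 1)")
    unknown <- setdiff(names(missing), tree$tip.label)
    if (length(unknown))
      stop("missing fractions for unknown genomes: ",
           paste(unknown, collapse = ", "))
    m[match(names(missing), tree$tip.label)] <- unname(missing)
  }
  labels <- character(B)
  labels[seq_len(nt)] <- tree$tip.label
  inode <- (nt + 1L):B
  labels[inode] <- if (!is.null(tree$node.label) &&
                       all(nzchar(tree$node.label)))
    tree$node.label else sprintf("node%d", inode)
  structure(list(tree = tree, n_leaves = nt, n_branches = B,
                 children = children, is_leaf = is_leaf, labels = labels,
                 m = m, root = nt + 1L),
            class = "phd_species_tree")
}

#' Read a species tree with a completeness sidecar TSV
#'
#' The sidecar has columns `genome` and `completeness` (fractions in
#' (0, 1]); the missing fraction used by the reconciliation is
#' `1 - completeness`.
#'
#' @param tree_path Newick file with a rooted binary tree.
#' @param completeness_path Optional TSV path.
#' @export
read_species_tree <- function(tree_path, completeness_path = NULL) {
  tr <- read_newick(tree_path)
  comp <- NULL
  if (!is.null(completeness_path)) {
    tab <- utils::read.delim(completeness_path, stringsAsFactors = FALSE)
    comp <- stats::setNames(tab$completeness, tab$genome)
  }
  species_tree(tr, completeness = comp)
}

#' DTL event rates
#'
#' @param delta Duplication rate (>= 0).
#' @param tau Transfer rate (>= 0).
#' @param lambda Loss rate (>= 0).
#' @export
dtl_rates <- function(delta, tau, lambda) {
  vals <- c(delta = delta, tau = tau, lambda = lambda)
  if (any(!is.finite(vals)) || any(vals < 0))
    stop("DTL rates must be finite and non-negative")
  structure(as.list(vals), class = "phd_dtl_rates")
}

event_probs <- function(rates) {
  Z <- 1 + rates$delta + rates$tau + rates$lambda
  list(S = 1 / Z, D = rates$delta / Z, T = rates$tau / Z,
       L = rates$lambda / Z)
}

#' Per-branch extinction probabilities under the undated DTL model
#'
#' Solves the fixed point
#' `E_e = P_L + P_S * s_e + P_D * E_e^2 + P_T * E_e * Ebar_-e`
#' where `s_e = E_f * E_g` on internal branches, `s_e = m_e` on leaf
#' branches (a present copy escapes observation with the missing
#' fraction), and `Ebar_-e` is the mean extinction over the other
#' branches.  Iterated from `E = 0` to a max change below 1e-10.
#'
#' @param stree A [species_tree()].
#' @param rates A [dtl_rates()].
#' @return Numeric vector `E` of length `n_branches`.
#' @export
extinction_probs <- function(stree, rates) {
  p <- event_probs(rates)
  B <- stree$n_branches
  f <- stree$children[, 1L]; g <- stree$children[, 2L]
  internal <- !stree$is_leaf
  E <- numeric(B)
  for (it in seq_len(10000L)) {
    s <- stree$m
    s[internal] <- E[f[internal]] * E[g[internal]]
    Ebar <- if (B > 1L) (sum(E) - E) / (B - 1L) else 0
    En <- p$L + p$S * s + p$D * E^2 + p$T * E * Ebar
    if (max(abs(En - E)) < 1e-10) return(En)
    E <- En
  }
  stop("extinction fixed point did not converge; residual ",
       max(abs(En - E)))
}

#' Gene family container
#'
#' @param id Family identifier.
#' @param counts Named integer vector of per-genome copy counts (>= 0).
#' @param tree Optional gene `phylo` (rooted or unrooted); when absent,
#'   families of size >= 2 are reconciled from the copy-count profile
#'   using an unresolved (star-like) topology.
#' @param leaf_map Optional named vector mapping gene tip labels to genome
#'   names; by default a tip label is used directly, or its trailing
#'   `"_<number>"` copy suffix is stripped.
#' @param ccp Optional [ccp_from_trees()] result; takes precedence over
#'   `tree` and amalgamates the likelihood over the sampled topologies.
#' @export
gene_family <- function(id, counts, tree = NULL, leaf_map = NULL,
                        ccp = NULL) {
  counts <- counts[counts > 0]
  size <- sum(counts)
  if (size < 1L) stop("gene family must contain at least one copy")
  structure(list(id = id, counts = counts, size = size, tree = tree,
                 leaf_map = leaf_map, ccp = ccp),
            class = "phd_gene_family")
}

map_tip_to_genome <- function(tips, leaf_map, genomes) {
  if (!is.null(leaf_map)) {
    g <- unname(leaf_map[tips])
    if (anyNA(g)) stop("gene leaves missing from leaf_map: ",
                       paste(tips[is.na(g)], collapse = ", "))
  } else {
    g <- ifelse(tips %in% genomes, tips, sub("_[0-9]+$", "", tips))
  }
  bad <- !(g %in% genomes)
  if (any(bad))
    stop("gene leaves map to unknown species: ",
         paste(tips[bad], collapse = ", "))
  g
}

# ---- clade graph -----------------------------------------------------------
# The DP runs over a "clade graph": gene-leaf subsets with weighted binary
# splits.  A rooted gene tree gives one split per clade (weight 1); an
# unrooted tree gives a top clade whose splits are the edge bipartitions
# with uniform weights (= averaging the likelihood over rootings); a CCP
# set gives conditional split frequencies estimated from a tree sample.

clade_key <- function(idx) paste(sort(idx), collapse = ",")

new_clade_graph <- function(leaf_genomes) {
  env <- new.env(parent = emptyenv())
  env$keys <- character(0)
  env$size <- integer(0)
  env$leaf <- integer(0)       # gene leaf index for size-1 clades
  env$splits <- list()
  env$leaf_genomes <- leaf_genomes
  env
}

cg_add_clade <- function(cg, idx) {
  key <- clade_key(idx)
  pos <- match(key, cg$keys)
  if (!is.na(pos)) return(pos)
  cg$keys <- c(cg$keys, key)
  cg$size <- c(cg$size, length(idx))
  cg$leaf <- c(cg$leaf, if (length(idx) == 1L) idx else NA_integer_)
  cg$splits[[length(cg$keys)]] <- list()
  length(cg$keys)
}

cg_add_split <- function(cg, parent, i1, i2, w) {
  cg$splits[[parent]] <- c(cg$splits[[parent]], list(c(i1, i2, w)))
}

# leaf subsets under each node of a (possibly multifurcating) phylo
node_leafsets <- function(tree) {
  nt <- length(tree$tip.label)
  nn <- nt + tree$Nnode
  ls <- vector("list", nn)
  for (i in seq_len(nt)) ls[[i]] <- i
  edge <- stats::reorder(tree, "postorder")$edge
  for (e in seq_len(nrow(edge)))
    ls[[edge[e, 1L]]] <- c(ls[[edge[e, 1L]]], ls[[edge[e, 2L]]])
  ls
}

clade_graph_from_rooted <- function(tree, leaf_genomes) {
  if (!ape::is.binary(tree)) stop("rooted gene tree must be binary")
  cg <- new_clade_graph(leaf_genomes)
  ls <- node_leafsets(tree)
  nt <- length(tree$tip.label)
  edge <- stats::reorder(tree, "postorder")$edge
  kids <- split(edge[, 2L], edge[, 1L])
  add_node <- function(v) {
    if (v <= nt) return(cg_add_clade(cg, ls[[v]]))
    ch <- kids[[as.character(v)]]
    i1 <- add_node(ch[1L]); i2 <- add_node(ch[2L])
    self <- cg_add_clade(cg, ls[[v]])
    cg_add_split(cg, self, i1, i2, 1)
    self
  }
  cg$top <- add_node(nt + 1L)
  cg
}

clade_graph_from_unrooted <- function(tree, leaf_genomes) {
  nt <- length(tree$tip.label)
  if (nt == 2L) {
    cg <- new_clade_graph(leaf_genomes)
    i1 <- cg_add_clade(cg, 1L); i2 <- cg_add_clade(cg, 2L)
    top <- cg_add_clade(cg, c(1L, 2L))
    cg_add_split(cg, top, i1, i2, 1)
    cg$top <- top
    return(cg)
  }
  cg <- new_clade_graph(leaf_genomes)
  all_idx <- seq_len(nt)
  # directed subtrees: each edge read in both directions
  ls <- node_leafsets(tree)
  edge <- stats::reorder(tree, "postorder")$edge
  # build clades for every directed edge
  dir_clades <- list()
  ensure <- function(idx) cg_add_clade(cg, idx)
  # splits of a directed clade (away from edge): children in that direction
  kids <- split(edge[, 2L], edge[, 1L])
  # recursively register directed-down clades (below each edge)
  below_id <- integer(nrow(edge))
  for (e in seq_len(nrow(edge))) {   # postorder: children first
    ch <- edge[e, 2L]
    idx <- ls[[ch]]
    id <- ensure(idx)
    below_id[e] <- id
    if (ch > nt) {
      ce <- which(edge[, 1L] == ch)
      if (length(ce) == 2L)
        cg_add_split(cg, id, below_id[ce[1L]], below_id[ce[2L]], 1)
      else stop("unrooted gene tree has a multifurcation below node ", ch)
    }
  }
  # directed-up clades (complements) and the top clade
  top <- ensure(all_idx)
  # complement of each edge: handled by rooting on that edge
  n_e <- nrow(edge)
  up_id <- integer(n_e)
  preorder <- rev(seq_len(n_e))
  for (e in preorder) {
    par <- edge[e, 1L]; ch <- edge[e, 2L]
    comp <- setdiff(all_idx, ls[[ch]])
    id <- ensure(comp)
    up_id[e] <- id
    # split of the complement seen from edge e: the other edges at `par`
    sibs <- which(edge[, 1L] == par & edge[, 2L] != ch)
    pe <- which(edge[, 2L] == par)
    parts <- c(below_id[sibs], if (length(pe)) up_id[pe])
    if (length(parts) == 2L)
      cg_add_split(cg, id, parts[1L], parts[2L], 1)
    else if (length(parts) != 0L)
      stop("unrooted gene tree must be binary (basal trifurcation expected)")
  }
  # top clade: one rooting per edge, uniform weights; for edges at the
  # basal trifurcation the complement is already covered above
  for (e in seq_len(n_e))
    cg_add_split(cg, top, below_id[e], up_id[e], 1 / n_e)
  cg$top <- top
  cg
}

# Clade graph for a family without a resolved tree: size 1 leaf, size 2
# cherry, size 3 the single unrooted topology; larger treeless families
# are reconciled through a CCP built from a star-like resolution and are
# rejected here.
clade_graph_from_counts <- function(leaf_genomes) {
  n <- length(leaf_genomes)
  if (n > 3L)
    stop("families of size > 3 need a gene tree or CCP set")
  cg <- new_clade_graph(leaf_genomes)
  if (n == 1L) {
    cg$top <- cg_add_clade(cg, 1L)
    return(cg)
  }
  ids <- vapply(seq_len(n), function(i) cg_add_clade(cg, i), integer(1L))
  if (n == 2L) {
    top <- cg_add_clade(cg, 1:2)
    cg_add_split(cg, top, ids[1L], ids[2L], 1)
    cg$top <- top
    return(cg)
  }
  pairs <- list(c(1L, 2L), c(1L, 3L), c(2L, 3L))
  pair_ids <- vapply(pairs, function(p) cg_add_clade(cg, p), integer(1L))
  top <- cg_add_clade(cg, 1:3)
  for (j in seq_len(3L)) {
    cg_add_split(cg, pair_ids[j], ids[pairs[[j]][1L]],
                 ids[pairs[[j]][2L]], 1)
    cg_add_split(cg, top, pair_ids[j], ids[setdiff(1:3, pairs[[j]])], 1 / 3)
  }
  cg$top <- top
  cg
}

build_clade_graph <- function(family, stree) {
  genomes <- stree$labels[seq_len(stree$n_leaves)]
  if (!is.null(family$ccp)) {
    g <- map_tip_to_genome(family$ccp$leaves, family$leaf_map, genomes)
    return(ccp_to_graph(family$ccp, match(g, genomes)))
  }
  if (!is.null(family$tree)) {
    tips <- family$tree$tip.label
    g <- map_tip_to_genome(tips, family$leaf_map, genomes)
    sp <- match(g, genomes)
    cg <- if (ape::is.rooted(family$tree) && ape::is.binary(family$tree))
      clade_graph_from_rooted(family$tree, sp)
    else clade_graph_from_unrooted(ape::unroot(family$tree), sp)
    return(cg)
  }
  # from copy counts
  sp <- rep(match(names(family$counts), genomes), times = family$counts)
  if (anyNA(sp)) stop("gene leaves map to unknown species: ",
                      paste(names(family$counts)[is.na(match(names(family$counts), genomes))],
                            collapse = ", "))
  clade_graph_from_counts(sp)
}

# ---- the dynamic program ---------------------------------------------------

# P matrix (clades x branches) plus the quantities needed for sampling.
dtl_dp <- function(cg, stree, rates, E = NULL) {
  p <- event_probs(rates)
  if (is.null(E)) E <- extinction_probs(stree, rates)
  B <- stree$n_branches
  internal <- !stree$is_leaf
  f <- stree$children[, 1L]; g <- stree$children[, 2L]
  fi <- f[internal]; gi <- g[internal]
  Ebar <- if (B > 1L) (sum(E) - E) / (B - 1L) else rep(0, B)
  n_cl <- length(cg$keys)
  P <- matrix(0, n_cl, B)
  ord <- order(cg$size)
  for (ci in ord) {
    A <- numeric(B)
    if (cg$size[ci] == 1L) {
      sb <- cg$leaf_genomes[cg$leaf[ci]]
      A[sb] <- p$S * (1 - stree$m[sb])
    } else {
      for (s in cg$splits[[ci]]) {
        P1 <- P[s[1L], ]; P2 <- P[s[2L], ]; w <- s[3L]
        spl <- numeric(B)
        spl[internal] <- P1[fi] * P2[gi] + P1[gi] * P2[fi]
        T1 <- if (B > 1L) (sum(P1) - P1) / (B - 1L) else rep(0, B)
        T2 <- if (B > 1L) (sum(P2) - P2) / (B - 1L) else rep(0, B)
        A <- A + w * (p$S * spl + 2 * p$D * P1 * P2 +
                        p$T * (P1 * T2 + P2 * T1))
      }
    }
    Pc <- A
    for (it in seq_len(10000L)) {
      Tbar <- if (B > 1L) (sum(Pc) - Pc) / (B - 1L) else rep(0, B)
      SL <- numeric(B)
      SL[internal] <- Pc[fi] * E[gi] + Pc[gi] * E[fi]
      Pn <- A + p$S * SL + 2 * p$D * E * Pc + p$T * (Ebar * Pc + E * Tbar)
      if (max(abs(Pn - Pc)) < 1e-14) { Pc <- Pn; break }
      Pc <- Pn
    }
    P[ci, ] <- Pc
  }
  list(P = P, E = E, Ebar = Ebar, p = p, cg = cg, stree = stree,
       Prs = rowSums(P))
}

#' Family log-likelihood under the undated DTL model
#'
#' Dynamic program over gene-tree clades x species branches.  A gene copy
#' on a leaf branch is observed with probability `1 - m_e`; unrooted gene
#' trees are averaged over all rootings with a uniform prior; the
#' origination branch carries a uniform prior over species branches.  By
#' default the likelihood is conditioned on the family being observed at
#' all (division by `1 - mean(E)`), since families are defined from
#' observed proteins.
#'
#' @param family A [gene_family()].
#' @param stree A [species_tree()].
#' @param rates A [dtl_rates()].
#' @param condition_on_observation Condition on non-extinction (default
#'   TRUE).
#' @return Log-likelihood (scalar).
#' @export
family_loglik <- function(family, stree, rates,
                          condition_on_observation = TRUE) {
  cg <- build_clade_graph(family, stree)
  dp <- dtl_dp(cg, stree, rates)
  lik <- mean(dp$P[cg$top, ])
  if (condition_on_observation) lik <- lik / (1 - mean(dp$E))
  if (lik <= 0) return(-Inf)
  log(lik)
}

#' Maximum-likelihood DTL rates (Nelder-Mead in log-rate space)
#'
#' Maximizes the summed (conditioned) family log-likelihood for one family
#' or a pooled set of families sharing rates.
#'
#' @param families A [gene_family()] or list of them.
#' @param stree A [species_tree()].
#' @param init Initial `(delta, tau, lambda)` (default 0.01 each).
#' @param tol Relative convergence tolerance (default 1e-3).
#' @param condition_on_observation Passed to [family_loglik()].
#' @return A [dtl_rates()] with attributes `loglik` and `convergence`.
#' @export
estimate_rates <- function(families, stree, init = c(0.01, 0.01, 0.01),
                           tol = 1e-3, condition_on_observation = TRUE) {
  if (inherits(families, "phd_gene_family")) families <- list(families)
  graphs <- lapply(families, build_clade_graph, stree = stree)
  nll <- function(lr) {
    r <- dtl_rates(exp(lr[1L]), exp(lr[2L]), exp(lr[3L]))
    tot <- 0
    denom_E <- extinction_probs(stree, r)
    for (cg in graphs) {
      dp <- dtl_dp(cg, stree, r, E = denom_E)
      lik <- mean(dp$P[cg$top, ])
      if (condition_on_observation) lik <- lik / (1 - mean(denom_E))
      if (lik <= 0) return(1e10)
      tot <- tot - log(lik)
    }
    tot
  }
  opt <- stats::optim(log(init), nll, method = "Nelder-Mead",
                      control = list(reltol = tol, maxit = 500L))
  if (opt$convergence != 0 && opt$convergence != 1)
    stop("rate optimization failed: code ", opt$convergence,
         ", final value ", opt$value)
  out <- dtl_rates(exp(opt$par[1L]), exp(opt$par[2L]), exp(opt$par[3L]))
  attr(out, "loglik") <- -opt$value
  attr(out, "convergence") <- opt$convergence
  out
}

#' Genome-label automorphism count of a rooted gene tree
#'
#' [family_loglik()] follows the ALE convention: gene-tree leaves are
#' distinguishable (they are named sequences), so the likelihood refers
#' to the observed *labelled* topology.  A synthetic genealogy whose
#' copies within a genome are interchangeable occurs with that likelihood
#' divided by the number of genome-label automorphisms of the tree
#' (a factor 2 for every internal node whose two child subtrees have
#' identical genome-labelled shapes).  This helper computes that count so
#' generative outcome frequencies can be compared against the DP exactly.
#'
#' @param tree Rooted binary gene `phylo`.
#' @param leaf_map Optional tip -> genome mapping as in [gene_family()].
#' @return Integer automorphism count (>= 1).
#' @export
genome_label_automorphisms <- function(tree, leaf_map = NULL) {
  tips <- tree$tip.label
  genome <- if (!is.null(leaf_map)) unname(leaf_map[tips])
            else sub("_[0-9]+$", "", tips)
  nt <- length(tips)
  edge <- stats::reorder(tree, "postorder")$edge
  kids <- split(edge[, 2L], edge[, 1L])
  aut <- 1L
  shape <- function(v) {
    if (v <= nt) return(genome[v])
    ch <- kids[[as.character(v)]]
    s1 <- shape(ch[1L]); s2 <- shape(ch[2L])
    if (identical(s1, s2)) aut <<- aut * 2L
    if (s1 > s2) { tmp <- s1; s1 <- s2; s2 <- tmp }
    paste0("(", s1, ",", s2, ")")
  }
  shape(nt + 1L)
  aut
}
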