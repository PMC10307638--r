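# Ground-truthed synthetic data: species trees, DTL gene-family
# histories with incomplete sampling, rate-heterogeneous and
# compositionally non-stationary alignments, and the canned
# long-branch-attraction artefact scenario.

#' Simulate a Yule species tree
#'
#' @param n_leaves Number of leaves (>= 2).
#' @param birth Birth rate (default 1).
#' @param seed Integer seed.
#' @param completeness Optional named completeness vector passed through
#'   to [species_tree()].
#' @return A [species_tree()]; tip labels are `g1 ... gn`.
#' @export
simulate_species_tree <- function(n_leaves, birth = 1, seed = 1L,
                                  completeness = NULL) {
  if (n_leaves < 2L) stop("need at least 2 leaves")
  tr <- with_seed(seed, ape::rphylo(n_leaves, birth = birth, death = 0))
  tr$tip.label <- sprintf("g%d", seq_len(n_leaves))
  species_tree(tr, completeness = completeness)
}

#' Simulate one gene-family history under the undated DTL process
#'
#' The discrete generative counterpart of the reconciliation DP: a
#' lineage on branch `e` draws an event from \{speciation-or-leaf,
#' duplication, transfer, loss\} with probabilities `P_S, P_D, P_T, P_L`;
#' transfers send a copy to a uniformly chosen other branch; at a leaf,
#' each surviving copy is observed with probability `1 - m_e`.  Histories
#' with zero observed copies are discarded and redrawn when
#' `condition_on_observation` is set (mirroring the conditioned
#' likelihood), with the redraw count recorded.
#'
#' @param stree A [species_tree()].
#' @param rates A [dtl_rates()].
#' @param seed Integer seed.
#' @param origin Origination branch; `NULL` draws it uniformly.
#' @param condition_on_observation Redraw extinct histories (default
#'   TRUE).
#' @param rate_multipliers Optional `n_branches x 3` matrix of per-branch
#'   multipliers on (delta, tau, lambda), for clade-specific dynamics.
#' @param max_events Abort threshold for runaway growth.
#' @return A `phd_family_history`: `events` (type, branch, order),
#'   `true_copies` (lineages surviving each branch), `leaf_presence`
#'   (true copies per genome before sampling), `observed_counts` (named,
#'   after incomplete sampling), `tree` (rooted `phylo` over observed
#'   copies, tips `genome_i`; `NULL` for < 2 copies), `origin`,
#'   `redraws`.
#' @export
simulate_gene_family <- function(stree, rates, seed = 1L, origin = NULL,
                                 condition_on_observation = TRUE,
                                 rate_multipliers = NULL,
                                 max_events = 1e6) {
  B <- stree$n_branches
  base <- c(rates$delta, rates$tau, rates$lambda)
  probs <- t(vapply(seq_len(B), function(e) {
    r <- if (is.null(rate_multipliers)) base else base * rate_multipliers[e, ]
    Z <- 1 + sum(r)
    c(1 / Z, r[1L] / Z, r[2L] / Z, r[3L] / Z)   # S, D, T, L
  }, numeric(4L)))
  with_seed(seed, {
    redraws <- 0L
    repeat {
      h <- sim_family_once(stree, probs, origin, max_events)
      if (!condition_on_observation || sum(h$observed_counts) > 0L) break
      redraws <- redraws + 1L
      if (redraws > 1e6) stop("family never observed; rates degenerate")
    }
    h$redraws <- redraws
    h
  })
}

sim_family_once <- function(stree, probs, origin, max_events) {
  B <- stree$n_branches
  ch <- stree$children
  is_leaf <- stree$is_leaf
  m <- stree$m
  if (is.null(origin)) origin <- sample.int(B, 1L)
  ev_type <- character(0); ev_branch <- integer(0)
  true_copies <- numeric(B)
  leaf_presence <- numeric(B)
  obs_counter <- integer(B)
  n_events <- 0L
  rec <- function(type, e) {
    ev_type[length(ev_type) + 1L] <<- type
    ev_branch[length(ev_branch) + 1L] <<- e
  }
  sim <- function(e) {
    n_events <<- n_events + 1L
    if (n_events > max_events)
      stop("runaway gene-family growth (over ", max_events, " events)")
    u <- stats::runif(1L)
    p <- probs[e, ]
    if (u < p[1L]) {                       # speciation or leaf arrival
      true_copies[e] <<- true_copies[e] + 1
      if (is_leaf[e]) {
        leaf_presence[e] <<- leaf_presence[e] + 1
        rec("C", e)
        if (stats::runif(1L) >= m[e]) {
          obs_counter[e] <<- obs_counter[e] + 1L
          return(sprintf("%s_%d", stree$labels[e], obs_counter[e]))
        }
        return(NULL)
      }
      rec("S", e)
      l <- sim(ch[e, 1L]); r <- sim(ch[e, 2L])
      if (is.null(l)) return(r)
      if (is.null(r)) return(l)
      return(list(l, r))
    }
    if (u < p[1L] + p[2L]) {               # duplication
      rec("D", e)
      l <- sim(e); r <- sim(e)
      if (is.null(l)) return(r)
      if (is.null(r)) return(l)
      return(list(l, r))
    }
    if (u < p[1L] + p[2L] + p[3L]) {       # transfer
      h <- sample.int(B - 1L, 1L)
      if (h >= e) h <- h + 1L
      rec("T", h)
      l <- sim(e); r <- sim(h)
      if (is.null(l)) return(r)
      if (is.null(r)) return(l)
      return(list(l, r))
    }
    rec("L", e)                            # loss
    NULL
  }
  genealogy <- sim(origin)
  counts <- stats::setNames(obs_counter[seq_len(stree$n_leaves)],
                            stree$labels[seq_len(stree$n_leaves)])
  counts <- counts[counts > 0L]
  tree <- if (sum(counts) >= 2L)
    parse_newick(paste0(genealogy_newick(genealogy), ";"))
  else NULL
  structure(list(events = data.frame(type = ev_type, branch = ev_branch,
                                     order = seq_along(ev_type),
                                     stringsAsFactors = FALSE),
                 true_copies = true_copies,
                 leaf_presence = leaf_presence[seq_len(stree$n_leaves)],
                 observed_counts = counts, tree = tree, origin = origin),
            class = "phd_family_history")
}

genealogy_newick <- function(node) {
  if (is.character(node)) return(node)
  sprintf("(%s,%s)", genealogy_newick(node[[1L]]),
          genealogy_newick(node[[2L]]))
}

#' Turn a simulated family history into a [gene_family()]
#'
#' @param history A `phd_family_history`.
#' @param id Family identifier.
#' @export
as_gene_family <- function(history, id) {
  gene_family(id, history$observed_counts, tree = history$tree)
}

#' Heterogeneity specification for alignment simulation
#'
#' @param alpha Gamma shape for among-site rate variation (`NULL` for
#'   rate-homogeneous data).
#' @param k_cat Discrete-gamma categories used to draw site rates.
#' @param overrides Named list of equilibrium-frequency vectors; the name
#'   selects the branch: a tip label for a terminal branch, or
#'   `"tipA+tipB"` for the branch above the MRCA of those tips.  Each
#'   override rebuilds the rate matrix around the given frequencies
#'   (exchangeabilities kept), so the lineage drifts towards the
#'   overridden composition.
#' @export
heterogeneity_spec <- function(alpha = NULL, k_cat = 4L,
                               overrides = list()) {
  for (f in overrides)
    if (abs(sum(f) - 1) > 1e-6)
      stop("override frequencies must sum to 1")
  list(alpha = alpha, k_cat = as.integer(k_cat), overrides = overrides)
}

resolve_override_edges <- function(tree, overrides) {
  if (length(overrides) == 0L) return(integer(0))
  edge_child <- tree$edge[, 2L]
  vapply(names(overrides), function(nm) {
    tips <- strsplit(nm, "+", fixed = TRUE)[[1L]]
    node <- if (length(tips) == 1L) match(tips, tree$tip.label)
            else ape::getMRCA(tree, tips)
    if (is.na(node) || is.null(node)) stop("override names unknown tip(s): ", nm)
    e <- which(edge_child == node)
    if (length(e) != 1L) stop("no branch above ", nm)
    e
  }, integer(1L))
}

#' Simulate an alignment with rate variation and compositional shifts
#'
#' Site rates are drawn from the discrete-gamma categories of `spec`;
#' states evolve along the tree by branch-wise transition probabilities.
#' Branches with frequency overrides use a rate matrix rebuilt around the
#' overridden equilibrium.
#'
#' @param tree `phylo` with branch lengths.
#' @param model Base [substitution_model()].
#' @param spec A [heterogeneity_spec()].
#' @param L Number of columns (>= 1).
#' @param seed Integer seed.
#' @param alphabet Alphabet tag for the result.
#' @return List: `alignment`, `site_rates` (true per-column rates),
#'   `categories` (true rate category per column).
#' @export
simulate_alignment <- function(tree, model, spec = heterogeneity_spec(),
                               L, seed = 1L, alphabet = "AA20") {
  if (L < 1L) stop("L must be >= 1")
  k <- model$k
  syms <- alphabet_symbols(alphabet)
  if (length(syms) != k) stop("alphabet size does not match model")
  rates <- if (is.null(spec$alpha)) 1
           else discrete_gamma_rates(spec$alpha, spec$k_cat)
  ov_edge <- resolve_override_edges(tree, spec$overrides)
  ov_models <- lapply(spec$overrides, function(f)
    substitution_model(k, exchangeability = model$S, pi = f))
  with_seed(seed, {
    cat_idx <- sample.int(length(rates), L, replace = TRUE)
    r <- rates[cat_idx]
    nt <- length(tree$tip.label)
    nn <- nt + tree$Nnode
    states <- matrix(0L, nn, L)
    root <- nt + 1L
    states[root, ] <- sample.int(k, L, replace = TRUE, prob = model$pi)
    edge <- tree$edge
    ord <- rev(seq_len(nrow(edge)))   # reverse postorder: parents first
    po <- stats::reorder(tree, "postorder")
    for (e in rev(seq_len(nrow(po$edge)))) {
      par <- po$edge[e, 1L]; chd <- po$edge[e, 2L]
      len <- po$edge.length[e]
      eid <- which(edge[, 2L] == chd)
      mdl <- if (length(ov_edge) && eid %in% ov_edge)
        ov_models[[which(ov_edge == eid)[1L]]] else model
      for (c in unique(cat_idx)) {
        P <- transition_matrix(mdl, len * rates[c])
        for (s in seq_len(k)) {
          cols <- which(cat_idx == c & states[par, ] == s)
          if (length(cols))
            states[chd, cols] <- sample.int(k, length(cols), replace = TRUE,
                                            prob = P[s, ])
        }
      }
    }
    mat <- matrix(syms[states[seq_len(nt), ]], nrow = nt,
                  dimnames = list(tree$tip.label, NULL))
    list(alignment = alignment(mat, alphabet = alphabet,
                               symbols = if (grepl("^CUSTOM", alphabet)) syms),
         site_rates = r, categories = cat_idx)
  })
}

# Composition override used by the artefact scenario: mass is
# concentrated on one residue per SR4 bin while bin totals keep their
# background values, so the bias is strong at the amino-acid level but
# disappears after SR4 recoding.
convergent_composition <- function() {
  pi <- rep(0.2 / 20, 20)
  names(pi) <- AA20_SYMBOLS
  bin_total <- c(A = 6 / 20, C = 4 / 20, G = 5 / 20, T = 5 / 20)
  major <- c(A = "A", C = "C", G = "D", T = "F")
  scheme <- sr4_scheme()$bins
  for (b in names(bin_total)) {
    members <- names(scheme)[scheme == b]
    minor <- setdiff(members, major[b])
    pi[major[b]] <- bin_total[b] * 0.85
    pi[minor] <- bin_total[b] * 0.15 / length(minor)
  }
  pi / sum(pi)
}

#' The canned long-branch-attraction artefact scenario
#'
#' A 17-taxon tree in which two phylogenetically distant lineages -- one
#' inside the in-group (`njord1`) and one in the out-group (`kor1`) --
#' share a strong compositional override and elongated branches, and the
#' query clade (`euk1`, `euk2`, long stem, same override) truly attaches
#' next to a short-branch in-group lineage (`hod1`, `hod2`).  The
#' compositional convergence is concentrated within SR4 bins, so recoding
#' homogenizes it, and rate variation (alpha = 0.5) makes the fastest
#' sites saturate on the long branches.
#'
#' @param seed Integer seed.
#' @param L Alignment length (default 500).
#' @return Bundle: `tree` (true tree), `backbone` (query pruned),
#'   `alignment`, `site_rates` (truth), `query_taxa`, `candidates`
#'   (named clades: `true_sister`, `attractor`, `kor`, `heim`),
#'   `convergent` (the two convergent backbone lineages), `spec`.
#' @export
artifact_scenario <- function(seed = 1L, L = 500L) {
  nwk <- paste0(
    "((kor1:1.0,(out1:0.2,(out2:0.2,out3:0.2):0.15):0.2):0.3,",
    "(((thor1:0.2,thor2:0.2):0.2,(loki1:0.2,loki2:0.2):0.2):0.15,",
    "((njord1:1.0,(ger1:0.25,ger2:0.25):0.2):0.15,",
    "((heim1:0.2,heim2:0.2):0.15,",
    "((hod1:0.15,hod2:0.15):0.1,(euk1:0.25,euk2:0.25):0.8):0.1):0.1):0.1):0.3);")
  tree <- parse_newick(nwk)
  biased <- convergent_composition()
  spec <- heterogeneity_spec(alpha = 0.5, overrides = list(
    kor1 = biased, njord1 = biased, `euk1+euk2` = biased,
    euk1 = biased, euk2 = biased))
  model <- substitution_model(20)
  sim <- simulate_alignment(tree, model, spec, L = L, seed = seed)
  backbone <- ape::drop.tip(tree, c("euk1", "euk2"))
  list(tree = tree, backbone = backbone, alignment = sim$alignment,
       site_rates = sim$site_rates,
       query_taxa = c("euk1", "euk2"),
       candidates = list(true_sister = c("hod1", "hod2"),
                         attractor = "njord1",
                         kor = "kor1",
                         heim = c("heim1", "heim2")),
       convergent = c("njord1", "kor1"),
       spec = spec)
}

#' Clade-contrast scenario: one clade with shifted genome dynamics
#'
#' A 22-genome species tree (a 10-leaf focal clade `a1..a10` against a
#' 12-leaf reference clade `b1..b12`) on which gene families
#' evolve under base DTL rates, except that every branch inside the focal
#' clade has its duplication rate multiplied by `dup_mult` and its loss
#' rate by `loss_mult`.  Ground truth (full event histories) is returned
#' for every family, so inferred normalized event rates can be scored.
#'
#' @param seed Integer seed.
#' @param n_families Number of gene families (default 150).
#' @param origin `"root"` (default) originates every family on the root
#'   branch, emulating core-genome families ancestrally present across
#'   the tree -- the regime in which per-ancestor event counts are dense
#'   enough for group comparisons; `"uniform"` draws the origination
#'   branch uniformly, as the reconciliation's origination prior does.
#' @param base Base [dtl_rates()] (default `dtl_rates(0.05, 0.03, 0.3)`,
#'   a loss-dominated regime in which both the duplication excess and the
#'   loss deficit stay visible after normalizing by proteome size).
#' @param dup_mult,loss_mult Focal-clade multipliers (defaults 3 and 0.5).
#' @param missing Optional named per-genome missing fractions.
#' @return List: `stree`, `families` (list of [gene_family()]),
#'   `histories` (matching `phd_family_history` truths), `groups` (named
#'   branch-label -> group vector; `focal` vs `reference`),
#'   `rate_multipliers`, `base`.
#' @export
clade_contrast_scenario <- function(seed = 1L, n_families = 150L,
                                    base = dtl_rates(0.05, 0.03, 0.3),
                                    dup_mult = 3, loss_mult = 0.5,
                                    origin = c("root", "uniform"),
                                    missing = NULL) {
  origin <- match.arg(origin)
  nwk <- paste0("((((a1,a2),(a3,a4)),(((a5,a6),(a7,a8)),(a9,a10))),",
                "((((b1,b2),(b3,b4)),((b5,b6),(b7,b8))),",
                "((b9,b10),(b11,b12))));")
  st <- species_tree(parse_newick(nwk), missing = missing)
  focal_tips <- sprintf("a%d", 1:10)
  below <- tips_below(st$tree)
  in_focal <- vapply(seq_len(st$n_branches), function(b)
    all(st$labels[below[[b]]] %in% focal_tips), logical(1L))
  mult <- matrix(1, st$n_branches, 3L)
  mult[in_focal, 1L] <- dup_mult
  mult[in_focal, 3L] <- loss_mult
  ob <- if (origin == "root") st$root else NULL
  hist <- lapply(seq_len(n_families), function(i)
    simulate_gene_family(st, base,
                         seed = (as.numeric(seed) * 100003 + i) %% 2e9,
                         origin = ob, rate_multipliers = mult))
  fams <- lapply(seq_along(hist), function(i)
    as_gene_family(hist[[i]], sprintf("fam%03d", i)))
  groups <- stats::setNames(ifelse(in_focal, "focal", "reference"),
                            st$labels)
  list(stree = st, families = fams, histories = hist, groups = groups,
       rate_multipliers = mult, base = base)
}
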