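# Undated DTL reconciliation: extinction, likelihood, CCP, sampling,
# copy numbers, thresholds.

two_leaf_stree <- function(m = NULL)
  species_tree(ape::read.tree(text = "(g1:1,g2:1);"), missing = m)

three_leaf_stree <- function(m = NULL)
  species_tree(ape::read.tree(text = "((g1:1,g2:1):1,g3:1);"), missing = m)

test_that("extinction probabilities solve their fixed point", {
  st <- three_leaf_stree()
  expect_equal(extinction_probs(st, dtl_rates(0, 0, 0)), rep(0, 5))
  # leaf branches decouple when delta = tau = 0: E = (lambda + m)/(1 + lambda)
  st_m <- two_leaf_stree(m = c(g1 = 0.2, g2 = 0.4))
  lam <- 0.3
  E <- extinction_probs(st_m, dtl_rates(0, 0, lam))
  expect_equal(E[1L], (lam + 0.2) / (1 + lam), tolerance = 1e-9)
  expect_equal(E[2L], (lam + 0.4) / (1 + lam), tolerance = 1e-9)
  # internal: E_root = p_L + p_S E1 E2 (still closed-form at tau = delta = 0)
  expect_equal(E[3L], (lam + E[1L] * E[2L]) / (1 + lam), tolerance = 1e-9)
})

test_that("extinction matches Monte-Carlo extinction of the simulator", {
  st <- three_leaf_stree(m = c(g1 = 0.2, g2 = 0, g3 = 0.1))
  rates <- dtl_rates(0.08, 0.06, 0.12)
  E <- extinction_probs(st, rates)
  n <- 4000L
  for (o in c(1L, 4L)) {
    ext <- vapply(seq_len(n), function(i) {
      h <- simulate_gene_family(st, rates, seed = o * 100000L + i,
                                origin = o,
                                condition_on_observation = FALSE)
      sum(h$observed_counts) == 0L
    }, logical(1L))
    se <- sqrt(E[o] * (1 - E[o]) / n)
    expect_lt(abs(mean(ext) - E[o]), 3 * se + 1e-12)
  }
})

test_that("family likelihood equals exhaustive enumeration on 3-leaf toys", {
  st <- three_leaf_stree()
  for (rates in list(dtl_rates(0.03, 0.02, 0.04),
                     dtl_rates(0.05, 0, 0.08))) {
    pr <- enum_outcomes(st, rates, max_aux = 6)
    cases <- list(
      list(fam = gene_family("s", c(g1 = 1)), key = "g1"),
      list(fam = gene_family("c12", c(g1 = 1, g2 = 1),
                             tree = ape::read.tree(text = "(g1_1,g2_1);")),
           key = "(g1,g2)"),
      list(fam = gene_family("t3", c(g1 = 1, g2 = 1, g3 = 1),
                             tree = ape::read.tree(
                               text = "((g1_1,g2_1),g3_1);")),
           key = "((g1,g2),g3)"),
      list(fam = gene_family("dup", c(g1 = 2),
                             tree = ape::read.tree(text = "(g1_1,g1_2);")),
           key = "(g1,g1)"))
    for (cs in cases) {
      # the DP scores the labelled tree; an unordered genealogy occurs
      # 1/automorphisms as often
      aut <- if (is.null(cs$fam$tree)) 1L
             else genome_label_automorphisms(cs$fam$tree)
      lik <- exp(family_loglik(cs$fam, st, rates,
                               condition_on_observation = FALSE)) / aut
      expect_equal(lik, unname(pr[[cs$key]]), tolerance = 1e-6)
    }
    # conditioning divides by the observation probability
    lik_c <- exp(family_loglik(cases[[1L]]$fam, st, rates))
    expect_equal(lik_c,
                 unname(pr[["g1"]]) / (1 - mean(extinction_probs(st, rates))),
                 tolerance = 1e-6)
  }
})

test_that("likelihood with missing fractions matches enumeration", {
  st <- three_leaf_stree(m = c(g1 = 0.3, g2 = 0.2, g3 = 0.25))
  rates <- dtl_rates(0.03, 0.02, 0.04)
  pr <- enum_outcomes(st, rates, max_aux = 6)
  fam <- gene_family("c", c(g1 = 1, g3 = 1),
                     tree = ape::read.tree(text = "(g1_1,g3_1);"))
  expect_equal(exp(family_loglik(fam, st, rates,
                                 condition_on_observation = FALSE)),
               unname(pr[["(g1,g3)"]]), tolerance = 1e-6)
})

test_that("tau = 0 reduces to a duplication-loss model (independent enumeration)", {
  st <- two_leaf_stree()
  rates <- dtl_rates(0.06, 0, 0.09)
  pr <- enum_outcomes(st, rates, max_aux = 7)
  fam <- gene_family("dl", c(g1 = 2, g2 = 1),
                     tree = ape::read.tree(text = "((g1_1,g1_2),g2_1);"))
  aut <- genome_label_automorphisms(fam$tree)
  expect_equal(aut, 2L)
  expect_equal(exp(family_loglik(fam, st, rates,
                                 condition_on_observation = FALSE)) / aut,
               unname(pr[["((g1,g1),g2)"]]), tolerance = 1e-6)
})

test_that("unrooted gene trees average the likelihood over rootings", {
  st <- three_leaf_stree()
  rates <- dtl_rates(0.04, 0.03, 0.05)
  tips <- c("g1_1", "g2_1", "g3_1")
  unrooted <- ape::unroot(ape::read.tree(text = "((g1_1,g2_1),g3_1);"))
  fam_u <- gene_family("u", c(g1 = 1, g2 = 1, g3 = 1), tree = unrooted)
  rootings <- c("((g1_1,g2_1),g3_1);", "((g1_1,g3_1),g2_1);",
                "((g2_1,g3_1),g1_1);")
  liks <- vapply(rootings, function(nw)
    exp(family_loglik(gene_family("r", c(g1 = 1, g2 = 1, g3 = 1),
                                  tree = ape::read.tree(text = nw)),
                      st, rates, condition_on_observation = FALSE)),
    numeric(1L))
  expect_equal(exp(family_loglik(fam_u, st, rates,
                                 condition_on_observation = FALSE)),
               mean(liks), tolerance = 1e-9)
})

test_that("CCP construction counts clades and conditional splits", {
  t1 <- ape::read.tree(text = "((a,b),c);")
  ccp <- ccp_from_trees(rep(list(t1), 100L))
  expect_true(all(ccp$clade_freq == 1))
  t2 <- ape::read.tree(text = "((a,c),b);")
  ccp2 <- ccp_from_trees(c(rep(list(t1), 50L), rep(list(t2), 50L)))
  root_key <- paste(1:3, collapse = ",")
  ws <- vapply(ccp2$splits[[root_key]], `[[`, numeric(1L), "w")
  expect_equal(sort(ws), c(0.5, 0.5))
  for (key in names(ccp2$splits))
    expect_equal(sum(vapply(ccp2$splits[[key]], `[[`, numeric(1L), "w")),
                 1, tolerance = 1e-9)
  expect_error(ccp_from_trees(list(t1, ape::read.tree(text = "((a,b),d);"))),
               "inconsistent")
})

test_that("amalgamated CCP likelihood interpolates the sampled topologies", {
  st <- three_leaf_stree()
  rates <- dtl_rates(0.04, 0.03, 0.05)
  t1 <- ape::read.tree(text = "((g1_1,g2_1),g3_1);")
  t2 <- ape::read.tree(text = "((g1_1,g3_1),g2_1);")
  counts <- c(g1 = 1, g2 = 1, g3 = 1)
  l1 <- exp(family_loglik(gene_family("f", counts, tree = t1), st, rates))
  l2 <- exp(family_loglik(gene_family("f", counts, tree = t2), st, rates))
  ccp <- ccp_from_trees(c(rep(list(t1), 50L), rep(list(t2), 50L)))
  lc <- exp(family_loglik(gene_family("f", counts, ccp = ccp), st, rates))
  expect_equal(lc, (l1 + l2) / 2, tolerance = 1e-9)
})

test_that("rate estimation improves on its starting point and respects tau = 0", {
  st <- simulate_species_tree(6, seed = 3)
  truth <- dtl_rates(0.1, 0, 0.2)
  fams <- lapply(1:40, function(i)
    as_gene_family(simulate_gene_family(st, truth, seed = 500 + i),
                   paste0("f", i)))
  est <- estimate_rates(fams, st, init = c(0.05, 0.05, 0.05))
  init_ll <- sum(vapply(fams, family_loglik, numeric(1L), stree = st,
                        rates = dtl_rates(0.05, 0.05, 0.05)))
  expect_gte(attr(est, "loglik"), init_ll)
  expect_lt(est$tau, 0.03)
})

test_that("a forced duplication is sampled at frequency 1", {
  st <- two_leaf_stree()
  rates <- dtl_rates(0.05, 0, 0)   # no loss, no transfer
  fam <- gene_family("d", c(g1 = 2),
                     tree = ape::read.tree(text = "(g1_1,g1_2);"))
  rec <- sample_reconciliations(fam, st, rates, n = 50L, seed = 2L)
  dup <- rec$events[rec$events$type == "D", ]
  expect_equal(nrow(dup), 1L)
  expect_equal(dup$branch, 1L)     # g1's branch
  expect_equal(dup$freq, 1)
  expect_true(all(rec$events$freq >= 0 & rec$events$freq <= 1))
  rec2 <- sample_reconciliations(fam, st, rates, n = 50L, seed = 2L)
  expect_identical(rec$events, rec2$events)
})

test_that("sampled origination frequencies match the DP posterior", {
  st <- three_leaf_stree()
  rates <- dtl_rates(0.05, 0.04, 0.1)
  fam <- gene_family("c", c(g1 = 1, g2 = 1),
                     tree = ape::read.tree(text = "(g1_1,g2_1);"))
  cg <- phylodissect:::build_clade_graph(fam, st)
  dp <- phylodissect:::dtl_dp(cg, st, rates)
  post <- dp$P[cg$top, ] / sum(dp$P[cg$top, ])
  n <- 3000L
  rec <- sample_reconciliations(fam, st, rates, n = n, seed = 7L)
  ofreq <- vapply(seq_len(st$n_branches), function(b) {
    ev <- rec$events
    f <- ev$freq[ev$type == "O" & ev$branch == b]
    if (length(f)) f else 0
  }, numeric(1L))
  for (b in seq_len(st$n_branches)) {
    se <- sqrt(post[b] * (1 - post[b]) / n)
    expect_lt(abs(ofreq[b] - post[b]), 3 * se + 1e-9)
  }
})

test_that("every sampled reconciliation balances its event bookkeeping", {
  st <- three_leaf_stree(m = c(g1 = 0.2, g2 = 0.1, g3 = 0))
  rates <- dtl_rates(0.1, 0.08, 0.2)
  fam <- gene_family("b", c(g1 = 2, g2 = 1),
                     tree = ape::read.tree(text = "((g1_1,g1_2),g2_1);"))
  rec <- sample_reconciliations(fam, st, rates, n = 200L, seed = 11L)
  B <- st$n_branches
  parent <- integer(B)
  for (b in seq_len(B)) if (!st$is_leaf[b])
    parent[st$children[b, ]] <- b
  for (s in rec$samples) {
    cnt <- function(ty) tabulate(s$branch[s$type == ty], nbins = B)
    Sv <- cnt("S")
    produced <- cnt("O") + ifelse(parent > 0, Sv[pmax(parent, 1L)], 0) +
      cnt("T") + cnt("D")
    consumed <- cnt("L") + Sv + cnt("C")
    expect_equal(produced, consumed)
  }
})

test_that("copy numbers: exact single-copy tracking and HT correction direction", {
  st <- three_leaf_stree()
  r0 <- dtl_rates(0, 0, 0)
  fam <- gene_family("all", c(g1 = 1, g2 = 1, g3 = 1),
                     tree = ape::read.tree(text = "((g1_1,g2_1),g3_1);"))
  rec <- sample_reconciliations(fam, st, r0, n = 20L, seed = 1L)
  cn <- ancestral_copy_numbers(rec, st)
  expect_equal(cn$raw, rep(1, 5))
  expect_equal(cn$corrected, rep(1, 5))

  st_m <- three_leaf_stree(m = c(g1 = 0.3, g2 = 0.3, g3 = 0.3))
  rates <- dtl_rates(0.05, 0.02, 0.1)
  fam2 <- gene_family("p", c(g1 = 1, g3 = 1),
                      tree = ape::read.tree(text = "(g1_1,g3_1);"))
  rec2 <- sample_reconciliations(fam2, st_m, rates, n = 100L, seed = 3L)
  cn2 <- ancestral_copy_numbers(rec2, st_m)
  expect_true(all(cn2$corrected >= cn2$raw - 1e-12))
  expect_true(rec2$observability < 1)
})

test_that("with sampling-only noise, corrected leaf copies re-inflate towards truth", {
  st <- two_leaf_stree(m = c(g1 = 0.3, g2 = 0.3))
  r0 <- dtl_rates(0, 0, 0)
  raws <- corrs <- numeric(0)
  for (i in 1:120) {
    h <- simulate_gene_family(st, r0, seed = 9000 + i, origin = st$root)
    rec <- sample_reconciliations(as_gene_family(h, "x"), st, r0,
                                  n = 40L, seed = i)
    cn <- ancestral_copy_numbers(rec, st)
    raws <- c(raws, cn$raw[1:2]); corrs <- c(corrs, cn$corrected[1:2])
  }
  expect_lt(mean(raws), 0.9)            # truth is 1 at both leaves
  expect_gt(mean(corrs), mean(raws))
  expect_lt(abs(mean(corrs) - 1), 0.08)
})

test_that("observability never increases with the loss rate", {
  st <- three_leaf_stree(m = c(g1 = 0.1, g2 = 0.2, g3 = 0))
  obs <- vapply(c(0, 0.1, 0.3, 0.6, 1), function(lam)
    1 - mean(extinction_probs(st, dtl_rates(0.05, 0.05, lam))),
    numeric(1L))
  expect_true(all(diff(obs) < 1e-12))
})

test_that("event filtering and presence classes apply the reporting thresholds", {
  ev <- data.frame(type = "D", branch = 1L, clade = "x",
                   freq = c(0.31, 0.29, 0.3))
  kept <- filter_events(ev)
  expect_equal(kept$freq, c(0.31, 0.3))
  expect_equal(nrow(filter_events(ev[0, ])), 0L)

  expect_equal(classify_presence(c(0.35, 0.2, 0.05)),
               c("present", "maybe_present", "absent"))
  expect_equal(classify_presence(c(0.1, 0.3)),
               c("maybe_present", "maybe_present"))
  expect_error(classify_presence(-0.1), "non-negative")
})

test_that("singletons are originations at their leaf", {
  st <- three_leaf_stree()
  fam <- gene_family("s", c(g2 = 1))
  rec <- singleton_origination(fam, st)
  o <- rec$events[rec$events$type == "O", ]
  expect_equal(o$branch, 2L)
  expect_equal(o$freq, 1)
  expect_equal(rec$copies, c(0, 1, 0, 0, 0))
  expect_equal(sum(rec$events$type == "O"), 1L)
  expect_error(singleton_origination(gene_family("d", c(g1 = 2)), st),
               "size 1")
})
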