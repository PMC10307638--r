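# The ground-truthed simulators.

test_that("Yule species trees have the requested size and are seed-stable", {
  st <- simulate_species_tree(2, seed = 1)
  expect_equal(st$n_leaves, 2L)
  expect_equal(st$n_branches, 3L)
  for (n in c(5, 12)) {
    st <- simulate_species_tree(n, seed = 7)
    expect_equal(length(st$tree$tip.label), n)
  }
  expect_identical(write_newick(simulate_species_tree(9, seed = 5)$tree),
                   write_newick(simulate_species_tree(9, seed = 5)$tree))
  expect_error(simulate_species_tree(1), "at least 2")
})

test_that("the zero-rate process yields exactly one observed copy per leaf", {
  st <- simulate_species_tree(6, seed = 2)
  h <- simulate_gene_family(st, dtl_rates(0, 0, 0), seed = 3, origin = st$root)
  expect_equal(unname(h$observed_counts[st$labels[1:6]]), rep(1L, 6))
  expect_equal(h$true_copies, rep(1, st$n_branches))
  expect_equal(sort(h$tree$tip.label), sort(sprintf("g%d_1", 1:6)))
})

test_that("incomplete sampling thins observed copies binomially", {
  st <- species_tree(ape::read.tree(text = "(g1:1,g2:1);"),
                     missing = c(g1 = 0.3, g2 = 0.3))
  n <- 4000L
  obs <- vapply(seq_len(n), function(i) {
    h <- simulate_gene_family(st, dtl_rates(0, 0, 0), seed = i,
                              origin = st$root,
                              condition_on_observation = FALSE)
    sum(h$observed_counts)
  }, numeric(1L))
  se <- sqrt(2 * 0.7 * 0.3 / n)
  expect_lt(abs(mean(obs) - 2 * 0.7), 3 * se)
})

test_that("family survival frequency matches the extinction computation", {
  st <- simulate_species_tree(4, seed = 9,
                              completeness = c(g1 = 0.8, g2 = 0.9,
                                               g3 = 1, g4 = 0.85))
  rates <- dtl_rates(0.06, 0.04, 0.15)
  surv_pred <- 1 - mean(extinction_probs(st, rates))
  n <- 4000L
  surv <- vapply(seq_len(n), function(i) {
    h <- simulate_gene_family(st, rates, seed = 20000 + i,
                              condition_on_observation = FALSE)
    sum(h$observed_counts) > 0L
  }, logical(1L))
  se <- sqrt(surv_pred * (1 - surv_pred) / n)
  expect_lt(abs(mean(surv) - surv_pred), 3 * se)
})

test_that("conditioned simulation never returns an unobserved family", {
  st <- simulate_species_tree(4, seed = 9)
  rates <- dtl_rates(0.02, 0.02, 0.9)
  for (i in 1:50) {
    h <- simulate_gene_family(st, rates, seed = i)
    expect_gt(sum(h$observed_counts), 0L)
  }
})

test_that("alignment simulation: zero lengths give identical taxa, truth returned", {
  tr <- ape::read.tree(text = "((a:0,b:0):0,(c:0,d:0):0);")
  sim <- simulate_alignment(tr, substitution_model(4),
                            heterogeneity_spec(), L = 50, seed = 1,
                            alphabet = "SR4")
  expect_equal(nrow(unique(sim$alignment$states)), 1L)
  expect_length(sim$site_rates, 50L)
  expect_error(simulate_alignment(tr, substitution_model(4),
                                  heterogeneity_spec(), L = 0, seed = 1),
               "L must be")
})

test_that("an overridden lineage drifts to the override equilibrium", {
  tr <- ape::read.tree(text = "((a:0.1,b:0.1):0.1,shifted:25);")
  pi_shift <- c(0.55, 0.25, 0.15, 0.05)
  sim <- simulate_alignment(tr, substitution_model(4),
                            heterogeneity_spec(overrides =
                              list(shifted = pi_shift)),
                            L = 8000, seed = 12, alphabet = "SR4")
  freq <- taxon_composition(sim$alignment)$freq["shifted", ]
  se <- sqrt(pi_shift * (1 - pi_shift) / 8000)
  expect_true(all(abs(freq - pi_shift) < 4 * se))
  expect_error(heterogeneity_spec(overrides = list(x = c(0.5, 0.4))),
               "sum to 1")
})

test_that("simulated gamma heterogeneity is recovered by the estimator", {
  st <- simulate_species_tree(16, seed = 31)
  mod <- substitution_model(20)
  sim <- simulate_alignment(st$tree, mod, heterogeneity_spec(alpha = 0.5),
                            L = 800, seed = 31)
  expect_lt(abs(estimate_alpha(sim$alignment, st$tree, mod) - 0.5), 0.2)
})

test_that("the artefact scenario bundle is complete and seed-deterministic", {
  sc1 <- artifact_scenario(seed = 3, L = 150)
  sc2 <- artifact_scenario(seed = 3, L = 150)
  expect_identical(sc1$alignment$states, sc2$alignment$states)
  expect_identical(write_newick(sc1$tree), write_newick(sc2$tree))
  expect_setequal(sc1$query_taxa, c("euk1", "euk2"))
  expect_true(all(sc1$query_taxa %in% sc1$alignment$taxa))
  expect_false(any(sc1$query_taxa %in% sc1$backbone$tip.label))
  expect_true(all(unlist(sc1$candidates) %in% sc1$backbone$tip.label))
  expect_gte(length(sc1$backbone$tip.label) + length(sc1$query_taxa), 16L)
})

test_that("clade-contrast truth records elevated duplications in the focal clade", {
  sc <- clade_contrast_scenario(seed = 2, n_families = 60)
  st <- sc$stree
  B <- st$n_branches
  dup_counts <- rowSums(vapply(sc$histories, function(h)
    tabulate(h$events$branch[h$events$type == "D"], nbins = B),
    numeric(B)))
  foc <- sc$groups[st$labels] == "focal"
  expect_gt(sum(dup_counts[foc]) / sum(foc),
            sum(dup_counts[!foc]) / sum(!foc))
  expect_identical(
    vapply(sc$families, `[[`, "", "id"),
    vapply(clade_contrast_scenario(seed = 2, n_families = 60)$families,
           `[[`, "", "id"))
})
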