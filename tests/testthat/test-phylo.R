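# Likelihood engine, LogDet distances, NJ, bootstrap, placement.

test_that("pruning matches the identity and independence limits", {
  aln <- make_aln(c(a = "A", b = "A"), alphabet = "SR4")
  mod <- substitution_model(4)
  t0 <- ape::read.tree(text = "(a:0,b:0);")
  expect_equal(felsenstein_loglik(aln, t0, mod)$loglik, log(0.25),
               tolerance = 1e-10)
  tinf <- ape::read.tree(text = "(a:400,b:400);")
  expect_equal(felsenstein_loglik(aln, tinf, mod)$loglik, log(0.0625),
               tolerance = 1e-8)
})

test_that("pruning equals brute-force state enumeration on small trees", {
  set.seed(7)
  for (nt in 2:4) {
    tr <- ape::rtree(nt)
    m <- matrix(sample(c("A", "C", "G", "T", "-", "?"), nt * 5, TRUE,
                       prob = c(rep(0.22, 4), 0.06, 0.06)),
                nt, 5, dimnames = list(tr$tip.label, NULL))
    aln <- alignment(m, alphabet = "SR4")
    pi <- c(0.4, 0.3, 0.2, 0.1)
    mod <- substitution_model(4, pi = pi)
    mine <- felsenstein_loglik(aln, tr, mod)
    oracle <- brute_loglik(aln, tr, mod)
    expect_equal(mine$site_loglik, oracle$site_loglik, tolerance = 1e-8)
  }
})

test_that("pruning likelihood is invariant to re-rooting", {
  set.seed(3)
  tr <- ape::rtree(8)
  m <- matrix(sample(c("A", "C", "G", "T"), 8 * 40, TRUE), 8, 40,
              dimnames = list(tr$tip.label, NULL))
  aln <- alignment(m, alphabet = "SR4")
  mod <- substitution_model(4, pi = c(0.4, 0.3, 0.2, 0.1))
  base <- felsenstein_loglik(aln, tr, mod)$loglik
  for (node in c(3L, 6L)) {
    rr <- ape::root(ape::unroot(tr), node = 8L + node, resolve.root = TRUE)
    expect_equal(felsenstein_loglik(aln, rr, mod)$loglik, base,
                 tolerance = 1e-8)
  }
})

test_that("gamma site likelihoods average the category likelihoods", {
  set.seed(1)
  tr <- ape::rtree(5)
  m <- matrix(sample(c("A", "C", "G", "T"), 5 * 12, TRUE), 5, 12,
              dimnames = list(tr$tip.label, NULL))
  aln <- alignment(m, alphabet = "SR4")
  r <- discrete_gamma_rates(0.7, 4)
  expect_equal(mean(r), 1, tolerance = 1e-9)
  mod_g <- substitution_model(4, alpha = 0.7)
  per_cat <- sapply(r, function(rc) {
    tr2 <- tr; tr2$edge.length <- tr$edge.length * rc
    felsenstein_loglik(aln, tr2, substitution_model(4))$site_loglik
  })
  expect_equal(felsenstein_loglik(aln, tr, mod_g)$site_loglik,
               log(rowMeans(exp(per_cat))), tolerance = 1e-8)
})

test_that("LogDet distances are symmetric, near-zero on identical rows, and additive in expectation", {
  aln <- make_aln(c(a = strrep("ACGT", 30), b = strrep("ACGT", 30)),
                  alphabet = "SR4")
  d <- logdet_distance(aln)
  expect_true(isSymmetric(d))
  expect_equal(diag(d), c(a = 0, b = 0))
  expect_lt(d["a", "b"], 0.05)

  tr <- ape::read.tree(text = "((a:0.2,b:0.3):0.1,(c:0.15,d:0.25):0.1);")
  sim <- simulate_alignment(tr, substitution_model(4),
                            heterogeneity_spec(), L = 8000, seed = 4,
                            alphabet = "SR4")
  dd <- logdet_distance(sim$alignment)
  # four-point condition: the two large sums nearly equal
  s1 <- dd["a", "b"] + dd["c", "d"]
  s2 <- dd["a", "c"] + dd["b", "d"]
  s3 <- dd["a", "d"] + dd["b", "c"]
  big <- sort(c(s1, s2, s3), decreasing = TRUE)
  expect_lt(abs(big[1] - big[2]), 0.05)
  expect_gt(min(big[1], big[2]) - big[3], 0.1)
})

test_that("NJ recovers an additive 5-leaf matrix exactly and is order-invariant", {
  tr <- ape::read.tree(text =
    "((a:0.3,b:0.2):0.15,(c:0.25,(d:0.1,e:0.2):0.05):0.1);")
  d <- ape::cophenetic.phylo(tr)
  nj1 <- nj_tree(d)
  expect_equal(as.numeric(ape::dist.topo(ape::unroot(tr), nj1)), 0)
  perm <- sample(rownames(d))
  nj2 <- nj_tree(d[perm, perm])
  expect_equal(as.numeric(ape::dist.topo(nj1, nj2)), 0)
  expect_equal(sort(nj_tree(d[1:3, 1:3])$tip.label), c("a", "b", "c"))
  d[1, 2] <- NA
  expect_error(nj_tree(d), "missing")
})

test_that("bootstrap support is 1 on unambiguous data and deterministic", {
  tr <- ape::read.tree(text =
    "((a:0.15,b:0.15):0.2,(c:0.15,(d:0.1,e:0.1):0.15):0.2);")
  sim <- simulate_alignment(tr, substitution_model(4),
                            heterogeneity_spec(), L = 4000, seed = 2,
                            alphabet = "SR4")
  est <- function(a) nj_tree(logdet_distance(a))
  bs <- bootstrap_support(sim$alignment, est, n_reps = 30L, seed = 5L)
  expect_true(all(bs$support >= 0 & bs$support <= 1, na.rm = TRUE))
  expect_true(all(stats::na.omit(bs$support) == 1))
  bs2 <- bootstrap_support(sim$alignment, est, n_reps = 30L, seed = 5L)
  expect_identical(bs$support, bs2$support)
  expect_error(bootstrap_support(sim$alignment, est, n_reps = 0L), "n_reps")
})

test_that("placement ranks the true attachment edge first in a high-signal regime", {
  tr <- ape::read.tree(text = paste0(
    "((a1:0.1,a2:0.1):0.2,((b1:0.1,b2:0.1):0.2,",
    "((q1:0.1,q2:0.1):0.15,(c1:0.1,c2:0.1):0.1):0.2):0.1);"))
  sim <- simulate_alignment(tr, substitution_model(4),
                            heterogeneity_spec(), L = 3000, seed = 9,
                            alphabet = "SR4")
  backbone <- ape::drop.tip(tr, c("q1", "q2"))
  cands <- list(cc = c("c1", "c2"), aa = c("a1", "a2"), bb = c("b1", "b2"))
  res <- constrained_placement(sim$alignment, backbone, c("q1", "q2"),
                               cands, substitution_model(4))
  expect_equal(res$candidate[1L], "cc")
  # ranking invariant to candidate order
  res2 <- constrained_placement(sim$alignment, backbone, c("q1", "q2"),
                                cands[c(3, 1, 2)], substitution_model(4))
  expect_equal(res2$candidate, res$candidate)
  expect_equal(sort(res2$loglik), sort(res$loglik), tolerance = 1e-6)
  expect_error(constrained_placement(sim$alignment, backbone,
                                     c("q1", "q2"), list(),
                                     substitution_model(4)), "candidate")
})

test_that("symmetric candidate edges score equally on symmetric data", {
  # query sits exactly between two mirror-image cherries; constant data
  backbone <- ape::read.tree(text =
    "((a1:0.1,a2:0.1):0.2,(b1:0.1,b2:0.1):0.2);")
  m <- matrix("A", 5, 40,
              dimnames = list(c("a1", "a2", "b1", "b2", "q1"), NULL))
  aln <- alignment(m, alphabet = "SR4")
  res <- constrained_placement(aln, backbone, "q1",
                               list(A = c("a1", "a2"), B = c("b1", "b2")),
                               substitution_model(4))
  expect_equal(res$loglik[1L], res$loglik[2L], tolerance = 1e-3)
})

test_that("the treatment grid enumerates its cells and degenerates correctly", {
  sc <- artifact_scenario(seed = 1, L = 120)
  models <- list(AA20 = substitution_model(20), SR4 = substitution_model(4))
  grid <- treatment_grid(sc$alignment, sc$tree, models,
                         taxon_sets = list(none = character(0)),
                         recode_options = c(FALSE, TRUE),
                         fsr_fractions = c(0, 0.2),
                         backbone = sc$backbone,
                         query_taxa = sc$query_taxa,
                         candidates = sc$candidates[c("true_sister",
                                                      "attractor")])
  expect_equal(nrow(grid), 4L)
  single <- treatment_grid(sc$alignment, sc$tree, models,
                           taxon_sets = list(none = character(0)),
                           recode_options = FALSE, fsr_fractions = 0,
                           backbone = sc$backbone,
                           query_taxa = sc$query_taxa,
                           candidates = sc$candidates[c("true_sister",
                                                        "attractor")])
  expect_equal(nrow(single), 1L)
  untreated <- grid[grid$fraction == 0 & !grid$recoded, ]
  expect_equal(single$winner, untreated$winner)
  expect_equal(single$loglik, untreated$loglik, tolerance = 1e-6)
})
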