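# Gamma shape estimation, posterior site rates, deciles, FSR series.

toy_rate_setup <- function() {
  tr <- ape::read.tree(text =
    "((a:0.3,b:0.4):0.2,(c:0.35,d:0.25):0.15);")
  mod <- substitution_model(4, pi = c(0.4, 0.3, 0.2, 0.1))
  list(tr = tr, mod = mod)
}

test_that("posterior site rates equal direct category enumeration on a toy", {
  s <- toy_rate_setup()
  aln <- make_aln(c(a = "AACGT", b = "ACCGT", c = "AAGGT", d = "AACTT"),
                  alphabet = "SR4")
  alpha <- 0.6
  prof <- posterior_site_rates(aln, s$tr, s$mod, alpha, k = 4L)
  r <- discrete_gamma_rates(alpha, 4L)
  liks <- sapply(r, function(rc)
    exp(brute_loglik(aln, s$tr, s$mod, rate = rc)$site_loglik))
  expected <- drop(liks %*% r) / rowSums(liks)
  expect_equal(prof$site_rates, expected, tolerance = 1e-10)
  expect_equal(mean(prof$category_rates), 1, tolerance = 1e-9)
})

test_that("invariant columns rate below the mean; symmetric columns tie", {
  s <- toy_rate_setup()
  mod <- substitution_model(4)             # symmetric model
  aln <- make_aln(c(a = "AAC", b = "AGC", c = "AAT", d = "AAC"),
                  alphabet = "SR4")
  prof <- posterior_site_rates(aln, s$tr, mod, 0.5)
  expect_lt(prof$site_rates[1L], mean(prof$site_rates))
  # two columns identical up to state relabelling under a symmetric model
  tr_sym <- ape::read.tree(text = "((a:0.2,b:0.2):0.1,(c:0.2,d:0.2):0.1);")
  aln2 <- make_aln(c(a = "AC", b = "AC", c = "GT", d = "GT"),
                   alphabet = "SR4")
  prof2 <- posterior_site_rates(aln2, tr_sym, mod, 0.5)
  expect_equal(prof2$site_rates[1L], prof2$site_rates[2L],
               tolerance = 1e-10)
})

test_that("alpha estimation recovers truth and flags degenerate input", {
  st <- simulate_species_tree(16, seed = 21)
  mod <- substitution_model(20)
  sim <- simulate_alignment(st$tree, mod, heterogeneity_spec(alpha = 0.5),
                            L = 600, seed = 21)
  a <- estimate_alpha(sim$alignment, st$tree, mod)
  expect_lt(abs(a - 0.5), 0.2)
  hom <- simulate_alignment(st$tree, mod, heterogeneity_spec(),
                            L = 400, seed = 22)
  expect_gt(estimate_alpha(hom$alignment, st$tree, mod), 10)
  const <- alignment(matrix("A", 16, 30,
                            dimnames = list(st$tree$tip.label, NULL)))
  expect_error(estimate_alpha(const, st$tree, mod), "alpha undefined")
})

test_that("decile categories split near-equally with index tie-breaks", {
  prof <- structure(list(site_rates = rep(1, 20)), class = "phd_siterates")
  d20 <- categorize_deciles(prof)$decile
  expect_equal(as.vector(table(d20)), rep(2L, 10L))
  # all tied: category order follows column index
  expect_equal(d20, rep(1:10, each = 2L))
  prof23 <- structure(list(site_rates = rep(1, 23)),
                      class = "phd_siterates")
  sizes <- as.vector(table(categorize_deciles(prof23)$decile))
  expect_equal(sort(sizes, decreasing = TRUE), c(3L, 3L, 3L, rep(2L, 7L)))
  expect_error(categorize_deciles(structure(list(site_rates = rep(1, 9)),
                                            class = "phd_siterates")),
               "at least 10")
})

test_that("FSR series removes floor(f*L) fastest columns, nested", {
  rates <- c(5, 1, 4, 2, 3, 1, 2, 0.5, 6, 1, 2, 3, 0.2, 0.1, 7, 2, 1, 3,
             0.4, 0.6)
  aln <- make_aln(stats::setNames(
    rep(paste(rep("A", 20), collapse = ""), 2), c("x", "y")))
  prof <- structure(list(site_rates = rates), class = "phd_siterates")
  ser <- fsr_series(aln, prof, fractions = c(0.1, 0.2, 0.5))
  expect_equal(length(ser$masks[[1L]]), 18L)
  expect_false(any(c(14L, 8L) %in% ser$masks[[1L]]))  # two fastest (0-based)
  for (i in 1:2)
    expect_true(all(ser$masks[[i + 1L]] %in% ser$masks[[i]]))
  expect_error(fsr_series(aln, prof, fractions = c(0, 0.2)), "strictly")
  expect_error(fsr_series(aln, prof, fractions = 1), "strictly")
  short <- structure(list(site_rates = rates[1:10]),
                     class = "phd_siterates")
  expect_error(fsr_series(aln, short), "different alignment")
})

test_that("removed sites evolve faster than retained on simulated truth", {
  st <- simulate_species_tree(12, seed = 8)
  mod <- substitution_model(20)
  sim <- simulate_alignment(st$tree, mod, heterogeneity_spec(alpha = 0.5),
                            L = 400, seed = 8)
  a <- estimate_alpha(sim$alignment, st$tree, mod)
  prof <- posterior_site_rates(sim$alignment, st$tree, mod, a)
  ser <- fsr_series(sim$alignment, prof, fractions = 0.3)
  kept <- ser$masks[[1L]] + 1L
  removed <- setdiff(seq_len(400), kept)
  expect_gt(mean(sim$site_rates[removed]), mean(sim$site_rates[kept]))
})

test_that("treat_alignment composes removal then recoding, f = 0 is identity", {
  st <- simulate_species_tree(8, seed = 4)
  mod <- substitution_model(20)
  sim <- simulate_alignment(st$tree, mod, heterogeneity_spec(alpha = 0.5),
                            L = 200, seed = 4)
  aln <- sim$alignment
  expect_identical(treat_alignment(aln, st$tree, mod, 0)$states,
                   aln$states)
  out <- treat_alignment(aln, st$tree, mod, 0.2, sr4_scheme())
  expect_equal(out$n_cols, 200L - floor(0.2 * 200L))
  expect_equal(out$alphabet, "SR4")
  # equals the manual fsr -> recode chain
  a <- estimate_alpha(aln, st$tree, mod)
  prof <- posterior_site_rates(aln, st$tree, mod, a)
  manual <- recode_alignment(
    subset_columns(aln, fsr_series(aln, prof, 0.2)$masks[[1L]]),
    sr4_scheme())
  expect_identical(out$states, manual$states)
})
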