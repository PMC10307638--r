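# Per-site rate estimation on a fixed tree and fast-site removal series.

#' Maximum-likelihood gamma shape on a fixed tree
#'
#' One-dimensional bracketed optimization of the discrete-gamma
#' log-likelihood over alpha in [0.02, 100] (tolerance 1e-4), holding the
#' tree and branch lengths fixed.
#'
#' @param aln Alignment.
#' @param tree `phylo` with branch lengths; tips a subset of the taxa.
#' @param model A [substitution_model()] (its `alpha` slot is ignored).
#' @param k Number of discrete-gamma categories.
#' @return The ML shape estimate.
#' @export
estimate_alpha <- function(aln, tree, model, k = 4L) {
  prep <- lik_prep(aln, tree, model)
  if (!has_variable_sites(aln, tree$tip.label))
    stop("alpha undefined: alignment has no variable sites")
  f <- function(a)
    -sum(lik_pattern_loglik(prep, prep$tree$edge.length, alpha = a,
                            k_cat = k) * prep$w)
  stats::optimize(f, interval = c(0.02, 100), tol = 1e-4)$minimum
}

has_variable_sites <- function(aln, tips) {
  m <- aln$states[tips, , drop = FALSE]
  any(apply(m, 2L, function(col) {
    obs <- col[col %in% aln$symbols]
    length(unique(obs)) > 1L
  }))
}

#' Posterior-mean site rates under a discrete-gamma model
#'
#' For each column, the posterior mean over the `k` equal-probability
#' category rates: `r_i = sum_c r_c L_i(r_c) / sum_c L_i(r_c)`, with site
#' likelihoods from pruning on branch lengths scaled by `r_c`.
#'
#' @inheritParams estimate_alpha
#' @param alpha Gamma shape (e.g. from [estimate_alpha()]).
#' @return A `phd_siterates` profile: `alpha`, `k`, `category_rates`
#'   (mean 1), `site_rates` (per column), `decile` (`NULL` until
#'   [categorize_deciles()]).
#' @export
posterior_site_rates <- function(aln, tree, model, alpha, k = 4L) {
  prep <- lik_prep(aln, tree, model)
  r <- discrete_gamma_rates(alpha, k)
  ll <- vapply(r, function(rc) lik_core(prep, prep$tree$edge.length, rc),
               numeric(prep$npat))
  if (prep$npat == 1L) ll <- matrix(ll, nrow = 1L)
  mx <- apply(ll, 1L, max)
  wgt <- exp(ll - mx)
  post <- drop(wgt %*% r) / rowSums(wgt)
  structure(list(alpha = alpha, k = k, category_rates = r,
                 site_rates = post[prep$pat_id], decile = NULL),
            class = "phd_siterates")
}

#' Classify columns into 10 rate categories (1 = fastest)
#'
#' Columns are sorted by decreasing posterior-mean rate (ties broken by
#' column index) and split into 10 near-equal blocks whose sizes differ by
#' at most one; larger blocks come first.
#'
#' @param profile A `phd_siterates` profile.
#' @export
categorize_deciles <- function(profile) {
  r <- profile$site_rates
  L <- length(r)
  if (L < 10L) stop("need at least 10 columns for decile categories, got ", L)
  ord <- order(-r, seq_along(r))
  sizes <- rep(L %/% 10L, 10L)
  extra <- L %% 10L
  if (extra > 0L) sizes[seq_len(extra)] <- sizes[seq_len(extra)] + 1L
  dec <- integer(L)
  dec[ord] <- rep(seq_len(10L), times = sizes)
  profile$decile <- dec
  profile
}

#' Nested fast-site-removal series
#'
#' For each fraction `f`, removes the `floor(f * L)` highest-rate columns
#' (stable ordering: decreasing rate, then column index), so retained sets
#' are nested across increasing fractions.
#'
#' @param aln Alignment the profile was computed on.
#' @param profile A `phd_siterates` profile for `aln`.
#' @param fractions Fractions in (0, 1), default `seq(0.1, 0.9, 0.1)`.
#' @return A `phd_removal_series`: `fractions` and `masks`, a list of
#'   retained 0-based column indices per fraction.
#' @export
fsr_series <- function(aln, profile, fractions = seq(0.1, 0.9, by = 0.1)) {
  if (length(profile$site_rates) != aln$n_cols)
    stop("profile was computed on a different alignment (",
         length(profile$site_rates), " vs ", aln$n_cols, " columns)")
  if (any(fractions <= 0 | fractions >= 1))
    stop("fractions must lie strictly in (0, 1)")
  fractions <- sort(fractions)
  L <- aln$n_cols
  ord <- order(-profile$site_rates, seq_len(L))   # fastest first
  masks <- lapply(fractions, function(f) {
    n_rm <- floor(f * L)
    sort(setdiff(seq_len(L), ord[seq_len(n_rm)])) - 1L
  })
  structure(list(fractions = fractions, masks = masks),
            class = "phd_removal_series")
}

#' Apply one fast-site-removal / recoding treatment
#'
#' The normative order of operations: site rates are estimated on the
#' amino-acid alignment, the fastest `floor(f * L)` columns are removed,
#' and only then is the surviving alignment (optionally) recoded.
#'
#' @param aln_aa `AA20` alignment.
#' @param tree Guide tree for rate estimation (an explicit input; no tree
#'   search happens implicitly).
#' @param model Model for rate estimation.
#' @param f Fraction of fastest sites to remove; `0` skips removal.
#' @param recode_scheme Optional recoding scheme, e.g. [sr4_scheme()].
#' @param alpha Optional fixed gamma shape; estimated when `NULL`.
#' @param k Number of gamma categories for rate estimation.
#' @return The treated alignment.
#' @export
treat_alignment <- function(aln_aa, tree, model, f, recode_scheme = NULL,
                            alpha = NULL, k = 4L) {
  if (aln_aa$alphabet != "AA20")
    stop("treatments start from an AA20 alignment, got ", aln_aa$alphabet)
  out <- aln_aa
  if (f > 0) {
    if (is.null(alpha)) alpha <- estimate_alpha(aln_aa, tree, model, k = k)
    prof <- posterior_site_rates(aln_aa, tree, model, alpha, k = k)
    series <- fsr_series(aln_aa, prof, fractions = f)
    out <- subset_columns(out, series$masks[[1L]])
  }
  if (!is.null(recode_scheme)) out <- recode_alignment(out, recode_scheme)
  out
}

#' Export per-site rates as TSV (column, rate, decile)
#'
#' @param profile A `phd_siterates` profile.
#' @param path Output path.
#' @export
write_site_rates_tsv <- function(profile, path) {
  utils::write.table(
    data.frame(column = seq_along(profile$site_rates) - 1L,
               rate = profile$site_rates,
               decile = if (is.null(profile$decile)) NA_integer_
                        else profile$decile),
    path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
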