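# Felsenstein pruning over site patterns, with per-pattern scaling.
#
# The engine works on an ape `phylo` tree whose tips are a subset of the
# alignment's taxa.  Gap '-', missing '?' and amino-acid ambiguity codes
# are fully ambiguous states.

# Precompute everything that does not depend on branch lengths: compressed
# site patterns, per-tip conditional-likelihood matrices, postorder edges.
lik_prep <- function(aln, tree, model) {
  if (length(model$pi) != length(aln$symbols))
    stop("model has ", length(model$pi), " states but alphabet ",
         aln$alphabet, " has ", length(aln$symbols))
  tips <- tree$tip.label
  missing_tips <- setdiff(tips, aln$taxa)
  if (length(missing_tips))
    stop("tree tips absent from alignment: ",
         paste(missing_tips, collapse = ", "))
  if (!is.null(tree$edge.length) && any(tree$edge.length < 0))
    stop("negative branch length in tree")
  m <- aln$states[tips, , drop = FALSE]
  k <- model$k
  # integer encoding: 1..k for states, 0 for ambiguous
  code <- match(m, aln$symbols)
  code[is.na(code)] <- 0L
  code <- matrix(code, nrow = nrow(m))
  pat_key <- apply(code, 2L, paste, collapse = ",")
  upat <- !duplicated(pat_key)
  pat_id <- match(pat_key, pat_key[upat])
  code_u <- code[, upat, drop = FALSE]
  w <- tabulate(pat_id, nbins = sum(upat))
  npat <- ncol(code_u)
  tippart <- vector("list", length(tips))
  for (i in seq_along(tips)) {
    p <- matrix(0, k, npat)
    st <- code_u[i, ]
    amb <- st == 0L
    p[, amb] <- 1
    if (any(!amb)) p[cbind(st[!amb], which(!amb))] <- 1
    tippart[[i]] <- p
  }
  po <- stats::reorder(tree, "postorder")
  list(tree = po, k = k, ntip = length(tips), npat = npat, w = w,
       pat_id = pat_id, tippart = tippart, pi = model$pi, eig = model$eig)
}

# Per-pattern log-likelihood for given edge lengths (in the prep's
# postorder edge order), optionally scaled by a rate multiplier.
lik_core <- function(prep, edge_len, rate = 1) {
  k <- prep$k; npat <- prep$npat
  edge <- prep$tree$edge
  nnode <- prep$ntip + prep$tree$Nnode
  partial <- vector("list", nnode)
  logsc <- vector("list", nnode)
  ev <- prep$eig$values; L <- prep$eig$left; R <- prep$eig$right
  for (e in seq_len(nrow(edge))) {
    par <- edge[e, 1L]; ch <- edge[e, 2L]
    P <- L %*% (exp(ev * (edge_len[e] * rate)) * R)
    P[P < 0] <- 0
    if (ch <= prep$ntip) {
      chp <- prep$tippart[[ch]]; chsc <- 0
    } else {
      # rescale completed internal child to avoid underflow
      mx <- do.call(pmax, c(asplit(partial[[ch]], 1L), list(1e-300)))
      chp <- partial[[ch]] / rep(mx, each = k)
      chsc <- logsc[[ch]] + log(mx)
    }
    contrib <- P %*% chp
    if (is.null(partial[[par]])) {
      partial[[par]] <- contrib
      logsc[[par]] <- chsc
    } else {
      partial[[par]] <- partial[[par]] * contrib
      logsc[[par]] <- logsc[[par]] + chsc
    }
  }
  root <- edge[nrow(edge), 1L]
  as.vector(log(drop(prep$pi %*% partial[[root]])) + logsc[[root]])
}

# Per-pattern log-likelihood averaged over discrete-gamma categories.
lik_pattern_loglik <- function(prep, edge_len, alpha = NULL, k_cat = 4L) {
  if (is.null(alpha)) return(lik_core(prep, edge_len))
  r <- discrete_gamma_rates(alpha, k_cat)
  ll <- vapply(r, function(rc) lik_core(prep, edge_len, rate = rc),
               numeric(prep$npat))
  if (prep$npat == 1L) ll <- matrix(ll, nrow = 1L)
  mx <- apply(ll, 1L, max)
  mx + log(rowMeans(exp(ll - mx)))
}

#' Total and per-site log-likelihood on a fixed tree (Felsenstein pruning)
#'
#' Standard pruning over alignment columns under a reversible model; gaps,
#' `'?'` and ambiguity codes are treated as fully ambiguous.  If the model
#' carries a gamma shape, the site likelihood is the equal-weight average
#' over the discrete-gamma categories.
#'
#' @param aln Alignment whose alphabet matches the model's state count.
#' @param tree `phylo` tree with branch lengths; tips must be a subset of
#'   the alignment's taxa.
#' @param model A [substitution_model()].
#' @return List with `loglik` (total) and `site_loglik` (per column).
#' @export
felsenstein_loglik <- function(aln, tree, model) {
  prep <- lik_prep(aln, tree, model)
  pl <- lik_pattern_loglik(prep, prep$tree$edge.length,
                           alpha = model$alpha, k_cat = model$k_cat)
  list(loglik = sum(pl * prep$w), site_loglik = pl[prep$pat_id])
}
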