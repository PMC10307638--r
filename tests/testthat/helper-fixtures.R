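# Shared fixtures and independent brute-force oracles.

make_aln <- function(seqs, alphabet = "AA20", symbols = NULL) {
  m <- do.call(rbind, lapply(seqs, function(s) strsplit(s, "")[[1L]]))
  rownames(m) <- names(seqs)
  alignment(m, alphabet = alphabet, symbols = symbols)
}

# Brute-force tree likelihood: sum over all internal-state assignments.
# Independent of the pruning engine (explicit enumeration).
brute_loglik <- function(aln, tree, model, rate = 1) {
  k <- model$k
  nt <- length(tree$tip.label)
  nn <- nt + tree$Nnode
  edge <- tree$edge
  Ps <- lapply(seq_len(nrow(edge)), function(e)
    transition_matrix(model, tree$edge.length[e] * rate))
  m <- aln$states[tree$tip.label, , drop = FALSE]
  code <- matrix(match(m, aln$symbols), nrow = nt)
  root <- nt + 1L
  internals <- (nt + 1L):nn
  per_site <- numeric(ncol(m))
  grid <- as.matrix(expand.grid(rep(list(seq_len(k)), length(internals))))
  for (col in seq_len(ncol(m))) {
    tot <- 0
    for (g in seq_len(nrow(grid))) {
      assign_state <- function(v) {
        if (v <= nt) return(code[v, col])          # NA = ambiguous
        grid[g, match(v, internals)]
      }
      pr <- model$pi[grid[g, match(root, internals)]]
      for (e in seq_len(nrow(edge))) {
        a <- assign_state(edge[e, 1L]); b <- assign_state(edge[e, 2L])
        pr <- pr * if (is.na(b)) 1 else Ps[[e]][a, b]
      }
      tot <- tot + pr
    }
    per_site[col] <- log(tot)
  }
  list(loglik = sum(per_site), site_loglik = per_site)
}

# Exact two-sided one-sample signed-rank p-value by enumeration of all
# 2^n sign assignments (midranks for ties).
brute_signedrank_p <- function(values, reference) {
  d <- values - reference
  d <- d[d != 0]
  n <- length(d)
  r <- rank(abs(d))
  W <- sum(r[d > 0])
  signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
  Ws <- signs %*% r
  ple <- mean(Ws <= W + 1e-12)
  pge <- mean(Ws >= W - 1e-12)
  min(1, 2 * min(ple, pge))
}

skip_slow <- function() invisible(TRUE)  # all tests always run
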