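# Exhaustive truncated enumeration of the undated DTL generative process,
# memoized on (branch, remaining auxiliary-event budget), vectorized over
# outcome pairs, restricted to outcomes with at most `max_leaves` observed
# copies (enumeration is monotone in observed copies, so larger outcomes
# can be dropped without affecting the retained probabilities).
enum_outcomes <- function(stree, rates, max_aux = 6, max_leaves = 3,
                          prune = 1e-13) {
  p <- phylodissect:::event_probs(rates)
  B <- stree$n_branches; ch <- stree$children
  is_leaf <- stree$is_leaf; m <- stree$m
  memo <- new.env(parent = emptyenv())
  nleaf <- function(g) ifelse(nzchar(g),
                              nchar(gsub("[^,]", "", g)) + 1L, 0L)
  combine <- function(l, r, fac) {
    pr <- as.vector(outer(l$pr, r$pr)) * fac
    gl <- rep(l$g, times = length(r$g))
    gr <- rep(r$g, each = length(l$g))
    keep <- pr >= prune & nleaf(gl) + nleaf(gr) <= max_leaves
    pr <- pr[keep]; gl <- gl[keep]; gr <- gr[keep]
    g <- ifelse(!nzchar(gl), gr,
         ifelse(!nzchar(gr), gl,
         ifelse(gl < gr, paste0("(", gl, ",", gr, ")"),
                          paste0("(", gr, ",", gl, ")"))))
    list(pr = pr, g = g)
  }
  squash <- function(res) {
    if (!length(res$pr)) return(list(pr = numeric(0), g = character(0)))
    agg <- tapply(res$pr, res$g, sum)
    list(pr = as.numeric(agg), g = names(agg))
  }
  sim <- function(e, aux) {
    key <- paste(e, aux)
    if (!is.null(memo[[key]])) return(memo[[key]])
    parts <- list()
    if (is_leaf[e]) {
      parts[[1]] <- list(pr = c(p$S * (1 - m[e]), if (m[e] > 0) p$S * m[e]),
                         g = c(stree$labels[e], if (m[e] > 0) ""))
    } else {
      parts[[1]] <- combine(sim(ch[e, 1], aux), sim(ch[e, 2], aux), p$S)
    }
    if (aux > 0) {
      if (p$L > 0) parts[[length(parts) + 1]] <- list(pr = p$L, g = "")
      if (p$D > 0) {
        s <- sim(e, aux - 1)
        parts[[length(parts) + 1]] <- combine(s, s, p$D)
      }
      if (p$T > 0) {
        s <- sim(e, aux - 1)
        for (h in setdiff(seq_len(B), e))
          parts[[length(parts) + 1]] <- combine(s, sim(h, aux - 1),
                                                p$T / (B - 1))
      }
    }
    res <- squash(list(pr = unlist(lapply(parts, `[[`, "pr")),
                       g = unlist(lapply(parts, `[[`, "g"))))
    memo[[key]] <- res
    res
  }
  tot <- list(pr = numeric(0), g = character(0))
  for (o in seq_len(B)) {
    s <- sim(o, max_aux)
    tot$pr <- c(tot$pr, s$pr / B); tot$g <- c(tot$g, s$g)
  }
  res <- squash(tot)
  out <- res$pr
  names(out) <- ifelse(nzchar(res$g), res$g, "extinct")
  sort(out, decreasing = TRUE)
}
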