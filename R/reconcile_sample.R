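# Stochastic backtracking of the reconciliation DP: sampled event
# histories, event frequencies, expected and corrected copy numbers.

#' Sample reconciliations by stochastic backtracking
#'
#' Draws `n` reconciled histories proportional to their contribution to
#' the DP likelihood.  Events are recorded per (type, species branch,
#' gene clade): `O` origination, `S` speciation (the lineage survives the
#' branch), `D` duplication, `T` transfer (recorded at the receiving
#' branch), `L` loss, `C` observed copy at a leaf.  A transfer whose
#' transferred copy goes extinct leaves no record.
#'
#' @param family A [gene_family()].
#' @param stree A [species_tree()].
#' @param rates A [dtl_rates()].
#' @param n Number of samples (default 100).
#' @param seed Integer seed.
#' @return A `phd_reconciliation`: `family_id`, `n`, `loglik`, `events`
#'   (data.frame `type`, `branch`, `clade`, `freq` where `freq` is the
#'   fraction of samples containing the event), `copies` (per-branch mean
#'   copy number: lineages surviving each branch), `samples` (list of
#'   per-sample event data.frames), `E` (extinction probabilities),
#'   `observability` (`O_g = 1 - mean(E)`).
#' @export
sample_reconciliations <- function(family, stree, rates, n = 100L,
                                   seed = 1L) {
  cg <- build_clade_graph(family, stree)
  dp <- dtl_dp(cg, stree, rates)
  lik <- mean(dp$P[cg$top, ])
  if (!is.finite(log(lik)))
    stop("family likelihood is zero; cannot sample reconciliations")
  B <- stree$n_branches
  samples <- with_seed(seed, lapply(seq_len(n), function(i)
    sample_one_reconciliation(dp, stree)))
  copies <- rowMeans(vapply(samples, function(s) {
    cp <- numeric(B)
    surv <- s$type %in% c("S", "C")
    if (any(surv)) {
      tb <- table(s$branch[surv])
      cp[as.integer(names(tb))] <- as.numeric(tb)
    }
    cp
  }, numeric(B)))
  key <- unlist(lapply(samples, function(s)
    unique(paste(s$type, s$branch, s$clade))))
  tb <- table(key)
  parts <- strsplit(names(tb), " ", fixed = TRUE)
  events <- data.frame(type = vapply(parts, `[`, "", 1L),
                       branch = as.integer(vapply(parts, `[`, "", 2L)),
                       clade = vapply(parts, `[`, "", 3L),
                       freq = as.numeric(tb) / n,
                       stringsAsFactors = FALSE)
  events <- events[order(events$type, events$branch, -events$freq), ]
  rownames(events) <- NULL
  O_g <- 1 - mean(dp$E)
  structure(list(family_id = family$id, n = n,
                 loglik = log(lik / O_g), events = events,
                 copies = copies, samples = samples, E = dp$E,
                 observability = O_g),
            class = "phd_reconciliation")
}

# One stochastic backtrack.  Returns a data.frame of events in the order
# they were drawn.  Term weights mirror the DP contributions; the per-step
# arithmetic is scalar (row sums of P cached in the DP object).
sample_one_reconciliation <- function(dp, stree) {
  cg <- dp$cg; p <- dp$p; E <- dp$E; P <- dp$P; Prs <- dp$Prs
  B <- stree$n_branches
  m <- stree$m
  ch <- stree$children
  is_leaf <- stree$is_leaf
  Ebar <- dp$Ebar
  cap <- 256L
  ev_type <- character(cap); ev_branch <- integer(cap)
  ev_clade <- character(cap); n_ev <- 0L
  rec <- function(type, e, ci) {
    n_ev <<- n_ev + 1L
    if (n_ev > cap) {
      cap <<- cap * 2L
      length(ev_type) <<- cap; length(ev_branch) <<- cap
      length(ev_clade) <<- cap
    }
    ev_type[n_ev] <<- type
    ev_branch[n_ev] <<- e
    ev_clade[n_ev] <<- cg$keys[ci]
  }
  pick <- function(w) sample.int(length(w), 1L, prob = w)
  other_pick <- function(weights, e) {
    w <- weights; w[e] <- 0
    pick(w)
  }
  stack <- matrix(0L, 2L, 64L); sp <- 0L
  push <- function(ci, e) {
    sp <<- sp + 1L
    if (sp > ncol(stack)) stack <<- cbind(stack, matrix(0L, 2L, ncol(stack)))
    stack[, sp] <<- c(ci, e)
  }
  o <- pick(P[cg$top, ])
  rec("O", o, cg$top)
  push(cg$top, o)
  guard <- 0L
  while (sp > 0L) {
    guard <- guard + 1L
    if (guard > 100000L) stop("runaway reconciliation sample")
    ci <- stack[1L, sp]; e <- stack[2L, sp]; sp <- sp - 1L
    f <- ch[e, 1L]; g <- ch[e, 2L]
    splits <- cg$splits[[ci]]
    ns <- length(splits)
    leaf_ok <- cg$size[ci] == 1L && cg$leaf_genomes[cg$leaf[ci]] == e
    # layout: [leaf] + per-split (S, D, T1, T2) + SLf SLg DL TL0 TLm
    terms <- numeric(1L + 4L * ns + 5L)
    if (leaf_ok) terms[1L] <- p$S * (1 - m[e])
    if (ns) for (si in seq_len(ns)) {
      s <- splits[[si]]
      i1 <- s[1L]; i2 <- s[2L]; w <- s[3L]
      off <- 1L + 4L * (si - 1L)
      if (!is_leaf[e])
        terms[off + 1L] <- w * p$S *
          (P[i1, f] * P[i2, g] + P[i1, g] * P[i2, f])
      terms[off + 2L] <- w * 2 * p$D * P[i1, e] * P[i2, e]
      terms[off + 3L] <- w * p$T * P[i1, e] * (Prs[i2] - P[i2, e]) / (B - 1L)
      terms[off + 4L] <- w * p$T * P[i2, e] * (Prs[i1] - P[i1, e]) / (B - 1L)
    }
    base <- 1L + 4L * ns
    if (!is_leaf[e]) {
      terms[base + 1L] <- p$S * P[ci, f] * E[g]
      terms[base + 2L] <- p$S * P[ci, g] * E[f]
    }
    terms[base + 3L] <- 2 * p$D * E[e] * P[ci, e]
    terms[base + 4L] <- p$T * Ebar[e] * P[ci, e]
    terms[base + 5L] <- p$T * E[e] * (Prs[ci] - P[ci, e]) / (B - 1L)
    a <- pick(terms)
    if (a == 1L) {                          # observed leaf copy
      rec("C", e, ci)
    } else if (a <= base) {
      si <- (a - 2L) %/% 4L + 1L
      kind <- (a - 2L) %% 4L
      s <- splits[[si]]; i1 <- s[1L]; i2 <- s[2L]
      if (kind == 0L) {                     # speciation
        rec("S", e, ci)
        w1 <- P[i1, f] * P[i2, g]; w2 <- P[i1, g] * P[i2, f]
        if (pick(c(w1, w2)) == 1L) { push(i1, f); push(i2, g) }
        else { push(i1, g); push(i2, f) }
      } else if (kind == 1L) {              # duplication
        rec("D", e, ci)
        push(i1, e); push(i2, e)
      } else {                              # transfer (kind 2: i2 moves)
        mover <- if (kind == 2L) i2 else i1
        stayer <- if (kind == 2L) i1 else i2
        h <- other_pick(P[mover, ], e)
        rec("T", h, mover)
        push(stayer, e); push(mover, h)
      }
    } else {
      kind <- a - base
      if (kind == 1L || kind == 2L) {       # speciation-loss
        rec("S", e, ci)
        lost <- if (kind == 1L) g else f
        kept <- if (kind == 1L) f else g
        rec("L", lost, ci)
        push(ci, kept)
      } else if (kind == 3L) {              # duplication-loss
        rec("D", e, ci); rec("L", e, ci)
        push(ci, e)
      } else if (kind == 4L) {              # transfer, transferee extinct
        push(ci, e)
      } else {                              # transfer, donor extinct
        h <- other_pick(P[ci, ], e)
        rec("T", h, ci); rec("L", e, ci)
        push(ci, h)
      }
    }
  }
  data.frame(type = ev_type[seq_len(n_ev)],
             branch = ev_branch[seq_len(n_ev)],
             clade = ev_clade[seq_len(n_ev)],
             stringsAsFactors = FALSE)
}

#' Keep events whose sampled frequency reaches the reporting threshold
#'
#' @param events Event data.frame with a `freq` column (e.g. from
#'   [sample_reconciliations()]).
#' @param theta_event Minimum raw reconciliation frequency (default 0.3).
#' @export
filter_events <- function(events, theta_event = 0.3) {
  events[events$freq >= theta_event, , drop = FALSE]
}

#' Raw and extinction-corrected ancestral copy numbers
#'
#' Raw per-branch copies are the mean number of lineages surviving each
#' species branch across sampled reconciliations; corrected copies divide
#' by the family observability `O_g = 1 - mean(E)`, a Horvitz-Thompson
#' style correction for gene families that escape observation entirely
#' (through loss or genome incompleteness).
#'
#' @param recon A [sample_reconciliations()] result.
#' @param stree The [species_tree()] used for the reconciliation.
#' @return `data.frame` with `branch`, `label`, `raw`, `corrected`.
#' @export
ancestral_copy_numbers <- function(recon, stree) {
  if (recon$observability <= 0)
    stop("family observability is zero; correction undefined")
  data.frame(branch = seq_len(stree$n_branches),
             label = stree$labels,
             raw = recon$copies,
             corrected = recon$copies / recon$observability,
             stringsAsFactors = FALSE)
}

#' Presence classes for an ancestral copy number
#'
#' `present` above 0.3, `maybe_present` between 0.1 and 0.3, `absent`
#' below 0.1.
#'
#' @param copy_number Numeric vector of copy numbers (>= 0).
#' @param theta_present Presence threshold (default 0.3, strict).
#' @param theta_maybe Lower bound of the maybe-present band (default 0.1).
#' @return Character vector in
#'   `{"present", "maybe_present", "absent"}`.
#' @export
classify_presence <- function(copy_number, theta_present = 0.3,
                              theta_maybe = 0.1) {
  if (any(copy_number < 0)) stop("copy numbers must be non-negative")
  ifelse(copy_number > theta_present, "present",
         ifelse(copy_number >= theta_maybe, "maybe_present", "absent"))
}

#' Singleton families are originations at their leaf
#'
#' A family with a single protein is scored as an origination on the
#' corresponding leaf branch, with copy number 1 there and 0 elsewhere;
#' no reconciliation DP is run.
#'
#' @param family A [gene_family()] of size 1.
#' @param stree A [species_tree()].
#' @return A `phd_reconciliation` with one `O` and one `C` event at
#'   frequency 1.
#' @export
singleton_origination <- function(family, stree) {
  if (family$size != 1L)
    stop("singleton_origination requires a family of size 1, got ",
         family$size)
  genome <- names(family$counts)
  b <- match(genome, stree$labels[seq_len(stree$n_leaves)])
  if (is.na(b)) stop("singleton genome not in species tree: ", genome)
  copies <- numeric(stree$n_branches)
  copies[b] <- 1
  events <- data.frame(type = c("O", "C"), branch = c(b, b),
                       clade = "1", freq = c(1, 1),
                       stringsAsFactors = FALSE)
  structure(list(family_id = family$id, n = 1L, loglik = 0,
                 events = events, copies = copies,
                 samples = list(data.frame(type = c("O", "C"),
                                           branch = c(b, b), clade = "1",
                                           stringsAsFactors = FALSE)),
                 E = NULL, observability = 1),
            class = "phd_reconciliation")
}
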