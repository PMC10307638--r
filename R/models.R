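# Reversible substitution models and discrete-gamma rate categories.

#' Construct a reversible substitution model
#'
#' A simple time-reversible k-state model: an exchangeability matrix (or
#' `"poisson"` for equal exchangeabilities) combined with equilibrium
#' frequencies, normalized to one expected substitution per site, with an
#' optional discrete-gamma rate distribution.
#'
#' @param k Alphabet size.
#' @param exchangeability `"poisson"` or a symmetric `k x k` matrix with
#'   zero diagonal.
#' @param pi Equilibrium frequencies (positive, summing to 1).
#' @param alpha Optional gamma shape for among-site rate variation.
#' @param k_cat Number of discrete-gamma categories (default 4).
#' @return A `phd_model` object carrying the normalized rate matrix and its
#'   eigendecomposition.
#' @export
substitution_model <- function(k, exchangeability = "poisson",
                               pi = rep(1 / k, k), alpha = NULL,
                               k_cat = 4L) {
  stopifnot(length(pi) == k)
  if (any(pi <= 0)) stop("equilibrium frequencies must be positive")
  pi <- pi / sum(pi)
  if (identical(exchangeability, "poisson")) {
    S <- matrix(1, k, k); diag(S) <- 0
  } else {
    S <- as.matrix(exchangeability)
    if (!isTRUE(all.equal(S, t(S))) || any(diag(S) != 0))
      stop("exchangeability matrix must be symmetric with zero diagonal")
  }
  Q <- S * rep(pi, each = k)      # q_ij = s_ij * pi_j
  diag(Q) <- -rowSums(Q)
  mu <- -sum(pi * diag(Q))        # expected rate
  Q <- Q / mu
  eig <- rev_eigen(Q, pi)
  if (!is.null(alpha) && alpha <= 0) stop("alpha must be positive")
  structure(list(k = k, S = S, pi = pi, Q = Q, eig = eig,
                 alpha = alpha, k_cat = as.integer(k_cat)),
            class = "phd_model")
}

# Eigendecomposition of a reversible Q via the symmetric similarity
# transform B = D^{1/2} Q D^{-1/2}.
rev_eigen <- function(Q, pi) {
  d <- sqrt(pi)
  B <- Q * (d %o% (1 / d))
  B <- (B + t(B)) / 2
  e <- eigen(B, symmetric = TRUE)
  list(values = e$values,
       left = e$vectors / d,            # D^{-1/2} V
       right = t(e$vectors) * rep(d, each = length(d)))  # V' D^{1/2}
}

#' Transition probability matrix P(t) under a model
#'
#' @param model A [substitution_model()].
#' @param t Branch length (expected substitutions per site), `t >= 0`.
#' @export
transition_matrix <- function(model, t) {
  if (t < 0) stop("negative branch length: ", t)
  P <- model$eig$left %*% (exp(model$eig$values * t) * model$eig$right)
  P[P < 0] <- 0
  P
}

#' Discrete-gamma category rates (equal-probability bins, bin-mean rates)
#'
#' Mean-normalized rates for `k` equal-probability categories of a
#' Gamma(alpha, alpha) distribution, each category rate being the
#' conditional mean within its bin.
#'
#' @param alpha Gamma shape (> 0).
#' @param k Number of categories.
#' @return Numeric vector of length `k`, mean exactly 1.
#' @export
discrete_gamma_rates <- function(alpha, k = 4L) {
  stopifnot(alpha > 0, k >= 1L)
  if (k == 1L) return(1)
  qb <- stats::qgamma(seq_len(k - 1L) / k, shape = alpha, rate = alpha)
  # E[X; X <= q] for Gamma(a, a) equals the Gamma(a + 1, a) cdf at q
  pb <- stats::pgamma(qb, shape = alpha + 1, rate = alpha)
  inc <- diff(c(0, pb, 1))
  r <- inc * k                      # conditional bin means (mean-1 overall)
  r / mean(r)
}
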