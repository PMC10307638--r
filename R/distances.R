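# Composition-robust distances, neighbour joining and bootstrap support.

#' LogDet (paralinear) pairwise distances
#'
#' For each taxon pair the k x k joint count matrix over shared ungapped
#' columns is formed (pseudocount 0.5 added to zero cells), and the
#' paralinear distance
#' `d = -(1/k) * (log det F - 0.5 * sum(log(row_i) + log(col_j)))`
#' is computed from the joint proportion matrix.  Pairs with no shared
#' columns (or a non-positive determinant, i.e. saturation) are flagged
#' missing (`NA`).
#'
#' @param aln Alignment with at least two taxa.
#' @return Symmetric distance matrix, zero diagonal, `NA` where undefined.
#' @export
logdet_distance <- function(aln) {
  nt <- length(aln$taxa)
  if (nt < 2L) stop("need at least 2 taxa")
  k <- length(aln$symbols)
  code <- match(aln$states, aln$symbols)
  code <- matrix(code, nrow = nt)
  d <- matrix(0, nt, nt, dimnames = list(aln$taxa, aln$taxa))
  for (i in seq_len(nt - 1L)) for (j in (i + 1L):nt) {
    ok <- !is.na(code[i, ]) & !is.na(code[j, ])
    if (!any(ok)) { d[i, j] <- d[j, i] <- NA_real_; next }
    F <- matrix(0, k, k)
    tab <- table(factor(code[i, ok], levels = seq_len(k)),
                 factor(code[j, ok], levels = seq_len(k)))
    F[] <- as.numeric(tab)
    F[F == 0] <- 0.5
    F <- F / sum(F)
    dt <- determinant(F, logarithm = TRUE)
    if (dt$sign <= 0) { d[i, j] <- d[j, i] <- NA_real_; next }
    val <- -(as.numeric(dt$modulus) -
               0.5 * (sum(log(rowSums(F))) + sum(log(colSums(F))))) / k
    d[i, j] <- d[j, i] <- max(val, 0)
  }
  d
}

#' Neighbour-joining tree from a complete distance matrix
#'
#' Standard NJ via \pkg{ape}; missing entries are rejected rather than
#' imputed.  Negative branch lengths produced by NJ are clamped to zero.
#'
#' @param d Symmetric distance matrix.
#' @return Unrooted `phylo` tree.
#' @export
nj_tree <- function(d) {
  d <- as.matrix(d)
  if (anyNA(d)) stop("distance matrix has missing entries")
  if (nrow(d) == 2L) {
    tr <- ape::read.tree(text = sprintf("(%s:%f,%s:%f);",
                                        rownames(d)[1L], d[1, 2] / 2,
                                        rownames(d)[2L], d[1, 2] / 2))
    return(tr)
  }
  tr <- ape::nj(stats::as.dist(d))
  tr$edge.length[tr$edge.length < 0] <- 0
  tr
}

#' Nonparametric bootstrap support for an alignment -> tree estimator
#'
#' Columns are resampled with replacement (within each partition when the
#' alignment carries a partition map); support for each internal branch of
#' the point-estimate tree is the fraction of replicate trees containing
#' the same bipartition.
#'
#' @param aln Alignment.
#' @param estimator Deterministic function `alignment -> phylo`.
#' @param n_reps Number of pseudoreplicates (default 100).
#' @param seed Integer seed for the resampling.
#' @return List with `tree` (point estimate, `node.label` set to support)
#'   and `support` (per internal node, root `NA`).
#' @export
bootstrap_support <- function(aln, estimator, n_reps = 100L, seed = 1L) {
  if (n_reps < 1L) stop("n_reps must be >= 1")
  point <- estimator(aln)
  blocks <- if (!is.null(aln$partition))
    lapply(seq_len(nrow(aln$partition)), function(i)
      (aln$partition$start[i] + 1L):aln$partition$end[i])
  else list(seq_len(aln$n_cols))
  reps <- with_seed(seed, lapply(seq_len(n_reps), function(r) {
    cols <- unlist(lapply(blocks, function(b) sample(b, length(b),
                                                     replace = TRUE)))
    estimator(subset_columns(aln, cols - 1L))
  }))
  counts <- ape::prop.clades(point, reps, rooted = FALSE)
  supp <- counts / n_reps
  point$node.label <- supp
  list(tree = point, support = supp)
}

with_seed <- function(seed, expr) {
  force(seed)
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  set.seed(seed)
  on.exit({
    if (is.null(old)) rm(".Random.seed", envir = globalenv())
    else assign(".Random.seed", old, envir = globalenv())
  })
  expr
}
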