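# Per-taxon compositional diagnostics: frequency tables, chi-square
# heterogeneity statistics, compositional distances and UPGMA ordering.

#' Per-taxon state composition of an alignment
#'
#' Frequencies are computed over non-gap, non-missing symbols only (for
#' amino-acid alignments, ambiguity codes are likewise excluded).
#'
#' @param aln Alignment.
#' @return A `phd_composition` table: `freq` (taxa x states matrix, rows
#'   sum to 1), `n` (ungapped symbol count per taxon), `mean_freq` (the
#'   unweighted across-taxon mean frequency vector).
#' @export
taxon_composition <- function(aln) {
  syms <- aln$symbols
  counts <- t(apply(aln$states, 1L, function(row)
    tabulate(match(row, syms), nbins = length(syms))))
  colnames(counts) <- syms
  n <- rowSums(counts)
  if (any(n == 0L))
    stop("taxon with no ungapped symbols: ",
         paste(aln$taxa[n == 0L], collapse = ", "))
  freq <- counts / n
  structure(list(freq = freq, n = n, mean_freq = colMeans(freq)),
            class = "phd_composition")
}

#' Per-taxon compositional chi-square statistic
#'
#' `X2_t = N_t * sum_s (f_ts - fbar_s)^2 / fbar_s`, where `fbar` is the
#' unweighted across-taxon mean composition; states absent from every
#' taxon are dropped.
#'
#' @param table A [taxon_composition()] result.
#' @return List with `per_taxon` (named vector) and `total`.
#' @export
composition_chisq <- function(table) {
  keep <- table$mean_freq > 0
  fbar <- table$mean_freq[keep]
  dev <- sweep(table$freq[, keep, drop = FALSE], 2L, fbar)
  x2 <- table$n * rowSums(sweep(dev^2, 2L, fbar, "/"))
  list(per_taxon = x2, total = sum(x2))
}

#' Pairwise compositional distances between taxa
#'
#' @param table A [taxon_composition()] result.
#' @param metric `"euclidean"` or `"jensen_shannon"` (the square-root JS
#'   divergence, a metric; base-2 logarithms so distances lie in [0, 1]).
#' @return Symmetric distance matrix with zero diagonal.
#' @export
composition_distance <- function(table, metric = c("euclidean",
                                                   "jensen_shannon")) {
  metric <- match.arg(metric)
  f <- table$freq
  if (nrow(f) < 2L) stop("need at least 2 taxa")
  if (metric == "euclidean")
    return(as.matrix(stats::dist(f, method = "euclidean")))
  nt <- nrow(f)
  d <- matrix(0, nt, nt, dimnames = list(rownames(f), rownames(f)))
  for (i in seq_len(nt - 1L)) for (j in (i + 1L):nt) {
    p <- f[i, ]; q <- f[j, ]; mid <- (p + q) / 2
    kl <- function(a, b) {
      nz <- a > 0
      sum(a[nz] * log2(a[nz] / b[nz]))
    }
    d[i, j] <- d[j, i] <- sqrt((kl(p, mid) + kl(q, mid)) / 2)
  }
  d
}

#' UPGMA dendrogram and leaf ordering for a distance matrix
#'
#' Average-linkage clustering with a deterministic tie-break (smallest
#' taxon index first), used to order compositional heatmaps.
#'
#' @param d Symmetric distance matrix with zero diagonal.
#' @return List with `hclust` (the dendrogram) and `order` (leaf labels in
#'   dendrogram order).
#' @export
upgma_order <- function(d) {
  d <- as.matrix(d)
  if (!isTRUE(all.equal(d, t(d), tolerance = 1e-12)))
    stop("distance matrix must be symmetric")
  # stats::hclust resolves ties by lowest index, matching the documented rule
  hc <- stats::hclust(stats::as.dist(d), method = "average")
  list(hclust = hc, order = hc$labels[hc$order])
}

#' Mutual compositional nearest neighbours
#'
#' Convenience diagnostic: returns TRUE when taxa `a` and `b` are each
#' other's nearest neighbour under the given compositional distance.
#'
#' @param d Compositional distance matrix.
#' @param a,b Taxon labels.
#' @export
mutual_nearest_neighbours <- function(d, a, b) {
  d <- as.matrix(d); diag(d) <- Inf
  nn <- function(x) names(which.min(d[x, ]))
  identical(nn(a), b) && identical(nn(b), a)
}

#' Write a composition table and chi-square statistics as TSV
#'
#' @param table A [taxon_composition()] result.
#' @param path Output path.
#' @export
write_composition_tsv <- function(table, path) {
  x2 <- composition_chisq(table)
  out <- data.frame(taxon = rownames(table$freq), n = table$n,
                    chisq = x2$per_taxon, table$freq,
                    check.names = FALSE)
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
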