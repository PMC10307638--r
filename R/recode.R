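# Reduced-alphabet recoding of amino-acid alignments.

#' The SR4 four-state recoding scheme
#'
#' The canonical Susko-Roger four-bin grouping of the 20 amino acids:
#' \{A,G,N,P,S,T\}, \{C,H,W,Y\}, \{D,E,K,Q,R\}, \{F,I,L,M,V\}.  Bin symbols
#' are written A, C, G, T so recoded alignments flow through four-state
#' machinery and standard nucleotide writers unchanged.
#'
#' @return A recoding scheme: list with `name`, `k`, and `bins` (named
#'   character vector mapping each amino acid to its bin symbol).
#' @export
sr4_scheme <- function() {
  bins <- c(A = "A", G = "A", N = "A", P = "A", S = "A", T = "A",
            C = "C", H = "C", W = "C", Y = "C",
            D = "G", E = "G", K = "G", Q = "G", R = "G",
            F = "T", I = "T", L = "T", M = "T", V = "T")
  recoding_scheme("SR4", bins)
}

#' Build a recoding scheme from a residue-to-bin mapping
#'
#' @param name Scheme name.
#' @param bins Named character vector: names are the 20 amino-acid symbols,
#'   values the bin symbols.  Every canonical amino acid must be mapped.
#' @export
recoding_scheme <- function(name, bins) {
  miss <- setdiff(AA20_SYMBOLS, names(bins))
  if (length(miss))
    stop("recoding scheme '", name, "' leaves residues unmapped: ",
         paste(miss, collapse = ", "))
  extra <- setdiff(names(bins), AA20_SYMBOLS)
  if (length(extra))
    stop("recoding scheme '", name, "' maps non-canonical symbols: ",
         paste(extra, collapse = ", "))
  structure(list(name = name, bins = bins[AA20_SYMBOLS],
                 k = length(unique(bins))),
            class = "phd_recoding_scheme")
}

#' Read a custom recoding scheme from TSV (columns: residue, bin)
#'
#' @param path TSV path.
#' @param name Scheme name (defaults to the file name).
#' @export
read_recoding_tsv <- function(path, name = basename(path)) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  bins <- stats::setNames(toupper(tab$bin), toupper(tab$residue))
  recoding_scheme(name, bins)
}

#' Recode an amino-acid alignment into a reduced alphabet
#'
#' Each residue is replaced by its bin symbol.  Gaps are preserved;
#' ambiguity codes (B, Z, J, X) and the rare residues U and O, which fall
#' outside the 20-state model, become `'?'` along with `'?'` itself.
#'
#' @param aln An `AA20` alignment.
#' @param scheme A recoding scheme, e.g. [sr4_scheme()].
#' @return An alignment with alphabet `"SR4"` (for the built-in scheme) or
#'   `"CUSTOM-k"`, same taxa and column count.
#' @export
recode_alignment <- function(aln, scheme = sr4_scheme()) {
  if (aln$alphabet != "AA20")
    stop("recoding requires an AA20 alignment, got ", aln$alphabet)
  map <- c(scheme$bins,
           stats::setNames(rep(MISSING_CHAR, 7L),
                           c("B", "Z", "J", "U", "O", "X", MISSING_CHAR)),
           stats::setNames(GAP_CHAR, GAP_CHAR))
  m <- aln$states
  out <- map[m]
  if (anyNA(out)) {
    idx <- which(is.na(matrix(out, nrow = nrow(m))), arr.ind = TRUE)[1L, ]
    stop(sprintf("unknown residue '%s' at taxon '%s', column %d",
                 m[idx[1L], idx[2L]], aln$taxa[idx[1L]], idx[2L] - 1L))
  }
  out <- matrix(out, nrow = nrow(m), dimnames = dimnames(m))
  bin_syms <- sort(unique(unname(scheme$bins)))
  tag <- if (identical(scheme$name, "SR4")) "SR4"
         else sprintf("CUSTOM-%d", scheme$k)
  alignment(out, alphabet = tag,
            symbols = if (tag == "SR4") NULL else bin_syms)
}
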