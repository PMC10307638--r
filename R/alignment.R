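# Alignment container and readers/writers.
#
# An alignment is a taxa x columns character matrix over a tagged alphabet.
# Gaps are '-', fully ambiguous/missing characters are '?'.  Columns are
# 0-based and partition intervals are half-open [start, end).

AA20_SYMBOLS <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
                  "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

GAP_CHAR <- "-"
MISSING_CHAR <- "?"

# Ambiguity/rare codes tolerated in AA20 input; treated as fully missing by
# every analysis and collapsed to '?' on recoding.
AA_AMBIG <- c("B", "Z", "J", "U", "O", "X")

#' Construct an alignment object
#'
#' Builds the container used by every treatment in the package: a character
#' matrix of single symbols with taxa as rows, an alphabet tag, and an
#' optional column partition map.
#'
#' @param states Character matrix (taxa x columns) of single-character
#'   symbols; rownames are taxon identifiers.
#' @param alphabet Alphabet tag: `"AA20"` (20 amino acids), `"SR4"`
#'   (four-state recoded, symbols A/C/G/T) or `"CUSTOM-k"` with `symbols`
#'   supplied.
#' @param symbols Symbol set for `CUSTOM-k` alphabets; ignored otherwise.
#' @param partition Optional partition map `data.frame` with columns
#'   `marker`, `start`, `end` (0-based, half-open) tiling `[0, ncol)`.
#' @return An object of class `phd_alignment` with elements `states`,
#'   `taxa`, `n_cols`, `alphabet`, `symbols`, `partition`.
#' @export
alignment <- function(states, alphabet = "AA20", symbols = NULL,
                      partition = NULL) {
  if (!is.matrix(states) || !is.character(states))
    stop("'states' must be a character matrix")
  taxa <- rownames(states)
  if (is.null(taxa)) stop("'states' must have taxon rownames")
  if (anyDuplicated(taxa))
    stop("duplicate taxon identifiers: ",
         paste(unique(taxa[duplicated(taxa)]), collapse = ", "))
  symbols <- alphabet_symbols(alphabet, symbols)
  states[] <- toupper(states)
  allowed <- c(symbols, GAP_CHAR, MISSING_CHAR)
  if (alphabet == "AA20") allowed <- c(allowed, AA_AMBIG)
  bad <- matrix(!(states %in% allowed), nrow = nrow(states))
  if (any(bad)) {
    idx <- which(bad, arr.ind = TRUE)[1L, ]
    stop(sprintf("symbol '%s' at taxon '%s', column %d not in alphabet %s",
                 states[bad][1L], taxa[idx[1L]], idx[2L] - 1L, alphabet))
  }
  if (!is.null(partition)) validate_partition(partition, ncol(states))
  structure(list(states = states, taxa = taxa, n_cols = ncol(states),
                 alphabet = alphabet, symbols = symbols,
                 partition = partition),
            class = "phd_alignment")
}

alphabet_symbols <- function(alphabet, symbols = NULL) {
  if (alphabet == "AA20") return(AA20_SYMBOLS)
  if (alphabet == "SR4") return(c("A", "C", "G", "T"))
  if (grepl("^CUSTOM-", alphabet)) {
    k <- as.integer(sub("^CUSTOM-", "", alphabet))
    if (is.null(symbols)) symbols <- default_bin_symbols(k)
    if (length(symbols) != k)
      stop("alphabet ", alphabet, " needs ", k, " symbols, got ",
           length(symbols))
    return(symbols)
  }
  stop("unknown alphabet tag: ", alphabet)
}

default_bin_symbols <- function(k) {
  pool <- c("A", "C", "G", "T", LETTERS[!LETTERS %in% c("A", "C", "G", "T")])
  if (k > length(pool)) stop("too many states for default symbols")
  pool[seq_len(k)]
}

validate_partition <- function(partition, L) {
  need <- c("marker", "start", "end")
  if (!all(need %in% names(partition)))
    stop("partition map needs columns marker, start, end")
  p <- partition[order(partition$start), , drop = FALSE]
  if (nrow(p) == 0 || p$start[1L] != 0L || p$end[nrow(p)] != L)
    stop("partition intervals must tile [0, ", L, ")")
  if (any(p$end <= p$start)) stop("empty partition interval")
  if (nrow(p) > 1 && any(p$start[-1L] != p$end[-nrow(p)]))
    stop("partition intervals must tile [0, ", L, ") without gaps/overlaps")
  invisible(p)
}

#' @export
print.phd_alignment <- function(x, ...) {
  cat(sprintf("<alignment: %d taxa x %d columns, alphabet %s%s>\n",
              length(x$taxa), x$n_cols, x$alphabet,
              if (!is.null(x$partition))
                sprintf(", %d partitions", nrow(x$partition)) else ""))
  invisible(x)
}

seq_to_chars <- function(s) strsplit(s, "", fixed = TRUE)[[1L]]

#' Read an alignment from FASTA or relaxed sequential PHYLIP
#'
#' Symbol case is normalised to upper case.  Ragged sequences and duplicate
#' taxon names are rejected.
#'
#' @param path File path.
#' @param format `"fasta"` or `"phylip"` (relaxed names, sequential).
#' @param alphabet Alphabet tag for the result (default `"AA20"`).
#' @param symbols Symbol set for custom alphabets.
#' @return A [alignment()] object.
#' @export
read_alignment <- function(path, format = c("fasta", "phylip"),
                           alphabet = "AA20", symbols = NULL) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("no such file: ", path)
  if (format == "fasta") {
    recs <- seqinr::read.fasta(path, seqtype = "AA", as.string = TRUE,
                               forceDNAtolower = FALSE, seqonly = FALSE)
    nm <- unname(vapply(recs, function(r) attr(r, "name"), character(1L)))
    seqs <- toupper(unlist(recs, use.names = FALSE))
  } else {
    seqs <- read_relaxed_phylip(path)
    nm <- names(seqs)
  }
  if (anyDuplicated(nm))
    stop("duplicate taxon identifiers in ", path, ": ",
         paste(unique(nm[duplicated(nm)]), collapse = ", "))
  lens <- nchar(seqs)
  if (length(unique(lens)) != 1L)
    stop(sprintf("ragged alignment in %s: taxon '%s' has length %d, expected %d",
                 path, nm[which(lens != lens[1L])[1L]],
                 lens[lens != lens[1L]][1L], lens[1L]))
  m <- do.call(rbind, lapply(seqs, seq_to_chars))
  rownames(m) <- nm
  alignment(m, alphabet = alphabet, symbols = symbols)
}

# Relaxed PHYLIP: header "ntax nchar", then whitespace-delimited name (up to
# 250 chars) followed by the full sequence, possibly wrapped over lines.
read_relaxed_phylip <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  hdr <- suppressWarnings(as.integer(strsplit(trimws(lines[1L]), "\\s+")[[1L]]))
  if (length(hdr) < 2L || anyNA(hdr[1:2]))
    stop("malformed PHYLIP header in ", path)
  ntax <- hdr[1L]; nchar_exp <- hdr[2L]
  body <- paste(lines[-1L], collapse = "\n")
  toks <- strsplit(trimws(body), "\\s+")[[1L]]
  seqs <- character(0); nms <- character(0)
  i <- 1L
  while (length(seqs) < ntax) {
    if (i > length(toks)) stop("truncated PHYLIP file: ", path)
    nms <- c(nms, toks[i]); i <- i + 1L
    s <- ""
    while (nchar(s) < nchar_exp) {
      if (i > length(toks)) stop("truncated sequence for taxon ", nms[length(nms)])
      s <- paste0(s, toks[i]); i <- i + 1L
    }
    if (nchar(s) != nchar_exp)
      stop(sprintf("ragged alignment: taxon '%s' has length %d, expected %d",
                   nms[length(nms)], nchar(s), nchar_exp))
    seqs <- c(seqs, toupper(s))
  }
  names(seqs) <- nms
  seqs
}

#' Write an alignment to FASTA or relaxed sequential PHYLIP
#'
#' @inheritParams read_alignment
#' @param aln A [alignment()] object.
#' @export
write_alignment <- function(aln, path, format = c("fasta", "phylip")) {
  format <- match.arg(format)
  seqs <- apply(aln$states, 1L, paste, collapse = "")
  if (format == "fasta") {
    seqinr::write.fasta(as.list(seqs), names = aln$taxa, file.out = path,
                        nbchar = 80)
  } else {
    con <- file(path, "w"); on.exit(close(con))
    writeLines(sprintf(" %d %d", length(aln$taxa), aln$n_cols), con)
    writeLines(paste(aln$taxa, seqs), con)
  }
  invisible(path)
}

#' Concatenate per-marker alignments into a supermatrix
#'
#' Taxa absent from a marker are padded with `'?'` (fully missing) across
#' that marker's interval, so downstream likelihoods treat the absent marker
#' as ambiguous rather than as gaps.
#'
#' @param alns List of alignments sharing one alphabet; names are used as
#'   marker names (defaults `marker1`, `marker2`, ...).
#' @param taxon_union If `TRUE` (default) the output covers the union of
#'   taxa; if `FALSE`, only taxa present in every marker are kept.
#' @return An alignment whose `partition` is the marker map tiling the
#'   result.
#' @export
concatenate_alignments <- function(alns, taxon_union = TRUE) {
  stopifnot(length(alns) >= 1L)
  tags <- vapply(alns, function(a) a$alphabet, character(1L))
  if (length(unique(tags)) != 1L)
    stop("mixed alphabets in concatenation: ", paste(unique(tags), collapse = ", "))
  if (is.null(names(alns)) || any(!nzchar(names(alns))))
    names(alns) <- sprintf("marker%d", seq_along(alns))
  taxa <- if (taxon_union) unique(unlist(lapply(alns, `[[`, "taxa")))
          else Reduce(intersect, lapply(alns, `[[`, "taxa"))
  if (length(taxa) == 0L) stop("no taxa shared across markers")
  lens <- vapply(alns, `[[`, integer(1L), "n_cols")
  L <- sum(lens)
  out <- matrix(MISSING_CHAR, nrow = length(taxa), ncol = L,
                dimnames = list(taxa, NULL))
  start <- 0L
  for (a in alns) {
    keep <- intersect(taxa, a$taxa)
    out[keep, seq_len(a$n_cols) + start] <- a$states[keep, , drop = FALSE]
    start <- start + a$n_cols
  }
  part <- data.frame(marker = names(alns),
                     start = cumsum(c(0L, lens[-length(lens)])),
                     end = cumsum(lens), row.names = NULL,
                     stringsAsFactors = FALSE)
  alignment(out, alphabet = tags[1L], symbols = alns[[1L]]$symbols,
            partition = part)
}

#' Drop taxa from an alignment
#'
#' Remaining taxa keep their original order.  With `prune_empty_cols`,
#' columns left with only gaps/missing symbols are removed and the
#' partition map re-indexed (markers reduced to zero length are dropped).
#'
#' @param aln Alignment.
#' @param drop Character vector of taxon identifiers to remove (must all be
#'   present).
#' @param prune_empty_cols Remove columns that became all-gap/missing.
#' @export
subset_taxa <- function(aln, drop, prune_empty_cols = FALSE) {
  drop <- as.character(drop)
  unknown <- setdiff(drop, aln$taxa)
  if (length(unknown))
    stop("unknown taxa: ", paste(unknown, collapse = ", "))
  keep <- setdiff(aln$taxa, drop)
  if (length(keep) == 0L) stop("cannot drop all taxa")
  m <- aln$states[keep, , drop = FALSE]
  part <- aln$partition
  if (prune_empty_cols) {
    empty <- colSums(m != GAP_CHAR & m != MISSING_CHAR) == 0L
    if (any(empty)) {
      if (!is.null(part)) {
        kept_per <- vapply(seq_len(nrow(part)), function(i) {
          cols <- (part$start[i] + 1L):part$end[i]
          sum(!empty[cols])
        }, integer(1L))
        part <- part[kept_per > 0L, , drop = FALSE]
        kept_per <- kept_per[kept_per > 0L]
        part$start <- cumsum(c(0L, kept_per[-length(kept_per)]))
        part$end <- cumsum(kept_per)
        rownames(part) <- NULL
      }
      m <- m[, !empty, drop = FALSE]
    }
  }
  alignment(m, alphabet = aln$alphabet, symbols = aln$symbols,
            partition = part)
}

#' Select alignment columns by 0-based index
#'
#' @param aln Alignment.
#' @param cols Integer vector of 0-based column indices to keep, in the
#'   order given.
#' @keywords internal
#' @export
subset_columns <- function(aln, cols) {
  stopifnot(all(cols >= 0L), all(cols < aln$n_cols))
  alignment(aln$states[, cols + 1L, drop = FALSE], alphabet = aln$alphabet,
            symbols = aln$symbols)
}

#' Read / write partition maps as TSV (marker, start, end)
#'
#' @param path TSV file path.
#' @export
read_partition_tsv <- function(path) {
  p <- utils::read.delim(path, stringsAsFactors = FALSE)
  p$start <- as.integer(p$start); p$end <- as.integer(p$end)
  p
}

#' @rdname read_partition_tsv
#' @param partition Partition map `data.frame`.
#' @export
write_partition_tsv <- function(partition, path) {
  utils::write.table(partition, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read and write Newick trees
#'
#' Thin wrappers around \pkg{ape} that keep parse errors informative and
#' quote labels containing Newick metacharacters on output.
#'
#' @param path Newick file path.
#' @return `read_newick`: an `ape` `phylo` object.
#' @export
read_newick <- function(path) {
  txt <- paste(readLines(path, warn = FALSE), collapse = "")
  parse_newick(txt)
}

parse_newick <- function(txt) {
  opens <- lengths(regmatches(txt, gregexpr("(", txt, fixed = TRUE)))
  closes <- lengths(regmatches(txt, gregexpr(")", txt, fixed = TRUE)))
  if (opens != closes)
    stop(sprintf("unbalanced parentheses in Newick (%d '(' vs %d ')')",
                 opens, closes))
  tr <- tryCatch(ape::read.tree(text = txt),
                 error = function(e) stop("Newick parse error: ",
                                          conditionMessage(e)))
  if (is.null(tr)) stop("Newick parse error near character ", nchar(txt))
  tr
}

#' @rdname read_newick
#' @param tree An `ape` `phylo` object.
#' @param digits Significant digits for branch lengths (default 10).
#' @export
write_newick <- function(tree, path = NULL, digits = 10) {
  txt <- ape::write.tree(tree, digits = digits)
  if (!is.null(path)) {
    writeLines(txt, path)
    return(invisible(path))
  }
  txt
}
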