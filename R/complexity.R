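#' Lempel-Ziv (LZ76) sequence complexity
#'
#' Counts the components of the Lempel-Ziv exhaustive parse of a symbol
#' string: scanning left to right, each new component is the shortest prefix
#' of the remaining text that cannot be reproduced (copying with self-overlap
#' allowed) from the text already parsed; a final, non-exhaustive component
#' counts once. The count is *not* normalized by sequence length. Repetitive
#' sequences parse into few components (a 19-mer homopolymer scores 2), while
#' a string of 19 distinct symbols scores 19; the count is a practical proxy
#' for hybridization specificity of a probe sequence.
#'
#' @param x Character vector of sequences (any symbols; case-sensitive).
#' @return Integer vector of production counts, one per sequence; each value
#'   lies in `[1, nchar(x)]`.
#' @examples
#' lz_complexity("abcdefghijklmnopqrs")                # 19
#' lz_complexity(strrep("A", 19))                      # 2
#' lz_complexity("ATATATATATATATATATA")                # 3
#' @export
lz_complexity <- function(x) {
  stopifnot(is.character(x))
  if (!length(x)) return(integer(0))
  if (anyNA(x) || any(!nzchar(x)))
    stop("sequences must be non-empty strings")
  lz76_cpp(x)
}

#' Sliding-window LZ76 complexity of a long sequence
#'
#' Computes [lz_complexity()] for every window of `window` consecutive
#' symbols, e.g. to profile the complexity of tiling 19-mers across an exome.
#'
#' @param sequence A single string with `nchar(sequence) >= window`.
#' @param window Window length in symbols (default 19).
#' @return Integer vector of length `nchar(sequence) - window + 1`, one value
#'   per window start position.
#' @export
tile_complexity <- function(sequence, window = 19L) {
  stopifnot(is.character(sequence), length(sequence) == 1L, !is.na(sequence))
  window <- as.integer(window)
  stopifnot(window >= 1L)
  if (nchar(sequence) < window)
    stop("sequence (length ", nchar(sequence),
         ") is shorter than the window (", window, ")")
  tile_lz76_cpp(sequence, window)
}

#' Sliding-window complexity of sequences in a FASTA file
#'
#' Reads a FASTA file, optionally concatenates all records in order (the
#' convention used to profile a contiguous exome assembly), and applies
#' [tile_complexity()].
#'
#' @param path Path to a FASTA file.
#' @param window Window length (default 19).
#' @param collapse If `TRUE` (default) concatenate all records into one
#'   string before tiling; otherwise return a list of per-record profiles.
#' @return Integer vector (collapsed) or named list of integer vectors.
#' @export
tile_complexity_fasta <- function(path, window = 19L, collapse = TRUE) {
  seqs <- as.character(Biostrings::readBStringSet(path))
  if (collapse)
    return(tile_complexity(paste(seqs, collapse = ""), window))
  lapply(seqs, tile_complexity, window = window)
}

#' Summarize a complexity distribution
#'
#' Mean, standard deviation, integer histogram and the fraction of sequences
#' at or above a complexity threshold, for a set of scored oligonucleotides.
#'
#' @param oligos A [generate_random_kmers()] result, an oligo record
#'   data frame with an `lz_complexity` column, or an integer vector of
#'   complexities.
#' @param threshold Complexity threshold for `fraction_at_or_above`
#'   (default 9, the complexity matched by typical exonic 19-mers).
#' @return An object of class `complexity_summary`: list with `n`, `mean`,
#'   `sd`, `histogram` (`breaks` = bin edges, `mids`, `probabilities` summing
#'   to 1), `threshold`, and `fraction_at_or_above` (exact count ratio).
#' @export
complexity_stats <- function(oligos, threshold = 9L) {
  cx <- if (inherits(oligos, "kmer_sample")) oligos$oligos$lz_complexity
        else if (is.data.frame(oligos))      oligos$lz_complexity
        else                                 oligos
  if (is.null(cx) || !length(cx))
    stop("no complexity values: empty oligo set")
  stopifnot(is.numeric(cx), !anyNA(cx))
  vals <- sort(unique(cx))
  breaks <- c(vals[1L] - 0.5, vals + 0.5)
  counts <- tabulate(match(cx, vals), nbins = length(vals))
  structure(list(
    n = length(cx),
    mean = mean(cx),
    sd = sd(cx),
    histogram = list(breaks = breaks, mids = vals,
                     probabilities = counts / length(cx)),
    threshold = threshold,
    fraction_at_or_above = sum(cx >= threshold) / length(cx)
  ), class = "complexity_summary")
}

#' @export
print.complexity_summary <- function(x, ...) {
  cat(sprintf("<complexity_summary> n = %d, mean = %.3f, sd = %.3f\n",
              x$n, x$mean, x$sd))
  cat(sprintf("  fraction with complexity >= %d: %.3f\n",
              x$threshold, x$fraction_at_or_above))
  invisible(x)
}
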