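#' Build oligo records from sequences
#'
#' Scores each sequence with its GC fraction, G count and LZ76 complexity.
#'
#' @param sequences Character vector of nucleotide sequences.
#' @return Data frame with columns `sequence`, `gc_fraction`, `g_count`,
#'   `lz_complexity`, `fold_energy` (kcal/mol, `NA` until annotated via
#'   [load_fold_energies()]).
#' @export
oligo_records <- function(sequences) {
  stopifnot(is.character(sequences))
  if (!length(sequences)) {
    return(data.frame(sequence = character(0), gc_fraction = numeric(0),
                      g_count = integer(0), lz_complexity = integer(0),
                      fold_energy = numeric(0), stringsAsFactors = FALSE))
  }
  sequences <- toupper(sequences)
  n <- nchar(sequences)
  gc <- (nchar(gsub("[^GC]", "", sequences))) / n
  g <- nchar(gsub("[^G]", "", sequences))
  data.frame(sequence = sequences,
             gc_fraction = gc,
             g_count = as.integer(g),
             lz_complexity = lz_complexity(sequences),
             fold_energy = NA_real_,
             stringsAsFactors = FALSE)
}

# Integer GC-count window implied by a fractional gc_range for length k,
# with inclusive bounds. Errors when no integer count is achievable.
gc_count_window <- function(gc_range, k) {
  stopifnot(is.numeric(gc_range), length(gc_range) == 2L,
            gc_range[1L] >= 0, gc_range[2L] <= 1, gc_range[1L] <= gc_range[2L])
  eps <- 1e-9
  lo <- ceiling(gc_range[1L] * k - eps)
  hi <- floor(gc_range[2L] * k + eps)
  if (lo > hi)
    stop(sprintf(paste0("gc_range [%g, %g] admits no integer GC count for ",
                        "k = %d: achievable counts are multiples c/%d; the ",
                        "requested window contains no integer c in [0, %d]"),
                 gc_range[1L], gc_range[2L], k, k, k))
  c(lo, hi)
}

#' Sample random k-mers over a restricted alphabet with a GC filter
#'
#' Draws sequences uniformly from `alphabet^k` without replacement (duplicate
#' integer codes are rejected) and retains those whose GC fraction lies in
#' `gc_range` (inclusive bounds). For a pure AUC alphabet the GC fraction is
#' just the C fraction, so with k = 19 and the default range only sequences
#' with 8-11 C residues survive.
#'
#' @param alphabet An [alphabet_spec()] (or string such as `"AUC"`).
#' @param k Oligo length (default 19).
#' @param n Number of draws.
#' @param gc_range Inclusive GC-fraction bounds, default `c(0.4, 0.6)`.
#' @param seed Optional integer seed; a fixed seed makes the sample
#'   reproducible, and the caller's RNG state is left untouched.
#' @return Object of class `kmer_sample`: list with `oligos` (an
#'   [oligo_records()] data frame of retained sequences), `alphabet`, `k`,
#'   `n_requested`, `n_drawn` (after duplicate rejection), `n_retained`,
#'   `yield` (= `n_retained / n_drawn`) and `gc_count_range`.
#' @examples
#' s <- generate_random_kmers("AUC", k = 19, n = 1000, seed = 1)
#' range(s$oligos$gc_fraction) * 19  # integer C counts within 8..11
#' @export
generate_random_kmers <- function(alphabet, k = 19L, n,
                                  gc_range = c(0.4, 0.6), seed = NULL) {
  alphabet <- as_alphabet(alphabet)
  k <- as.integer(k)
  n <- as.integer(n)
  stopifnot(k >= 1L, n >= 1L)
  win <- gc_count_window(gc_range, k)
  b <- length(alphabet$letters)

  digits <- with_seed(seed, {
    # draw digits directly (full RNG resolution), then reject duplicate
    # codes so the sample is without replacement over alphabet^k;
    # b^k <= 4^19 < 2^53 is exact in doubles
    m <- matrix(sample.int(b, n * k, replace = TRUE) - 1L, nrow = n)
    codes <- as.vector(m %*% b^(seq_len(k) - 1))
    m[!duplicated(codes), , drop = FALSE]
  })
  n_drawn <- nrow(digits)

  gc_idx <- which(alphabet$letters %in% c("G", "C")) - 1L
  gc_count <- if (length(gc_idx)) {
    rowSums(matrix(digits %in% gc_idx, nrow = n_drawn))
  } else rep(0L, n_drawn)
  keep <- gc_count >= win[1L] & gc_count <= win[2L]

  kept <- digits[keep, , drop = FALSE]
  letters_mat <- matrix(alphabet$letters[kept + 1L], nrow = nrow(kept))
  seqs <- do.call(paste0, as.data.frame(letters_mat, stringsAsFactors = FALSE))
  if (!nrow(kept)) seqs <- character(0)

  structure(list(
    oligos = oligo_records(seqs),
    alphabet = alphabet,
    k = k,
    n_requested = n,
    n_drawn = n_drawn,
    n_retained = length(seqs),
    yield = length(seqs) / n_drawn,
    gc_count_range = win
  ), class = "kmer_sample")
}

#' @export
print.kmer_sample <- function(x, ...) {
  cat(sprintf(
    "<kmer_sample> %s %d-mers: %d drawn, %d retained (yield %.3f, GC count %d..%d)\n",
    paste(x$alphabet$letters, collapse = ""), x$k, x$n_drawn, x$n_retained,
    x$yield, x$gc_count_range[1L], x$gc_count_range[2L]))
  invisible(x)
}
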