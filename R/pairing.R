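#' Maximum self base-pairing (structure-propensity proxy)
#'
#' Nussinov-style dynamic program returning the maximum number of nested
#' Watson-Crick plus G-U wobble pairs a sequence can form with itself, with
#' hairpin loops of at least `min_loop` unpaired bases. Higher values mean a
#' more structure-prone sequence. This is a combinatorial proxy for
#' self-folding propensity, not a thermodynamic model; nearest-neighbor free
#' energies from an external folding tool can be attached with
#' [load_fold_energies()].
#'
#' @param sequence Nucleotide string (RNA or DNA; T is treated as U for
#'   pairing purposes, so with `wobble = TRUE` the G-T/G-U wobble counts).
#' @param min_loop Minimum hairpin loop length in nucleotides (default 3).
#' @param wobble Include the G-U wobble pair (default TRUE; guanine's
#'   wobble pairing with uracil is one reason G-containing sequences fold).
#'   Note the score is invariant under reverse complementation only for
#'   Watson-Crick-only pairing (`wobble = FALSE`), since a G:U pair maps to
#'   an unpairable C:A.
#' @return Integer: the maximum number of simultaneous base pairs.
#' @examples
#' pairing_proxy(strrep("A", 19))   # 0
#' pairing_proxy("GGGGAAAACCCC")    # 4
#' @export
pairing_proxy <- function(sequence, min_loop = 3L, wobble = TRUE) {
  s <- check_sequence(sequence)
  min_loop <- as.integer(min_loop)
  stopifnot(min_loop >= 0L)
  code <- match(strsplit(chartr("T", "U", s), "")[[1L]],
                c("A", "U", "G", "C")) - 1L
  nussinov_cpp(code, min_loop, isTRUE(wobble))
}

# Extra pairs gained when a target is embedded in flanking context, relative
# to target and context folding independently; used by design_probes() to
# flag targets likely to be sequestered by their flanks.
context_excess_pairs <- function(target, context, min_loop = 3L) {
  joint <- pairing_proxy(paste0(context, target), min_loop)
  joint - pairing_proxy(target, min_loop) - pairing_proxy(context, min_loop)
}
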