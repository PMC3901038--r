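#' Restricted nucleotide alphabets
#'
#' An alphabet specification names the 3 or 4 nucleotide symbols a sequence
#' may use, together with its chemistry (RNA or DNA). Three-base alphabets
#' (AUC targets, ATG probes) are the basis of unstructured probe design:
#' removing one base removes most self-complementarity.
#'
#' @param letters Character vector of unique nucleotide symbols (3 or 4 of
#'   them), or a single string such as `"AUC"`. Case-insensitive; `U`/`T` are
#'   normalized to the alphabet kind.
#' @param kind `"RNA"` or `"DNA"`. If missing, inferred from the presence of
#'   `U` (RNA) or `T` (DNA); defaults to RNA when neither occurs.
#' @return An object of class `alphabet_spec` with elements `letters`
#'   (ordered, uppercase) and `kind`.
#' @examples
#' alphabet_spec("AUC")
#' alphabet_spec(c("A", "T", "G"))
#' @export
alphabet_spec <- function(letters, kind = NULL) {
  if (length(letters) == 1L && nchar(letters) > 1L)
    letters <- strsplit(letters, "")[[1L]]
  letters <- toupper(letters)
  if (is.null(kind)) {
    kind <- if ("T" %in% letters) "DNA" else "RNA"
  }
  kind <- match.arg(kind, c("RNA", "DNA"))
  letters <- chartr(if (kind == "RNA") "T" else "U",
                    if (kind == "RNA") "U" else "T", letters)
  valid <- if (kind == "RNA") c("A", "C", "G", "U") else c("A", "C", "G", "T")
  if (anyDuplicated(letters))
    stop("alphabet letters must be unique")
  if (!all(letters %in% valid))
    stop("invalid letters for ", kind, " alphabet: ",
         paste(setdiff(letters, valid), collapse = ", "))
  if (!length(letters) %in% c(3L, 4L))
    stop("an alphabet has 3 or 4 letters, got ", length(letters))
  structure(list(letters = letters, kind = kind), class = "alphabet_spec")
}

#' @export
print.alphabet_spec <- function(x, ...) {
  cat(sprintf("<alphabet_spec> %s (%s)\n",
              paste(x$letters, collapse = ""), x$kind))
  invisible(x)
}

as_alphabet <- function(x) {
  if (inherits(x, "alphabet_spec")) x else alphabet_spec(x)
}

# Uppercase a sequence and check it only uses symbols from `valid`.
check_sequence <- function(sequence, valid = c("A", "C", "G", "T", "U"),
                           what = "sequence") {
  stopifnot(is.character(sequence), length(sequence) == 1L)
  if (is.na(sequence) || !nzchar(sequence))
    stop(what, " must be a non-empty string")
  s <- toupper(gsub("[ \t]", "", sequence))
  bad <- setdiff(unique(strsplit(s, "")[[1L]]), valid)
  if (length(bad))
    stop("invalid symbol(s) in ", what, ": ", paste(bad, collapse = ", "))
  s
}

#' Count occurrences of a base in a sequence
#'
#' @param sequence A nucleotide string (case-insensitive, spaces ignored).
#' @param base A single nucleotide symbol.
#' @return Integer count of `base` in `sequence`.
#' @examples
#' residue_count("GTTAAGATAAGGGATAGGG", "G")  # 8
#' @export
residue_count <- function(sequence, base) {
  s <- check_sequence(sequence)
  stopifnot(is.character(base), length(base) == 1L, nchar(base) == 1L)
  b <- toupper(base)
  if (!b %in% c("A", "C", "G", "T", "U"))
    stop("invalid base: ", base)
  sum(strsplit(s, "")[[1L]] == b)
}

#' GC fraction of a sequence
#'
#' The fraction (#G + #C) / length; for pure-AUC sequences this is simply the
#' C fraction, and for pure-ATG sequences the G fraction.
#'
#' @inheritParams residue_count
#' @return Numeric fraction in \[0, 1\].
#' @export
gc_fraction <- function(sequence) {
  s <- check_sequence(sequence)
  ch <- strsplit(s, "")[[1L]]
  sum(ch %in% c("G", "C")) / length(ch)
}

#' Reverse-complement an RNA target into its DNA probe
#'
#' Maps a (nascent-RNA) target sequence onto the complementary DNA probe that
#' hybridizes to it. A pure three-base AUC target yields a pure ATG probe, the
#' construction that keeps both strands of the pair unstructured.
#'
#' @param rna_target RNA sequence over A, U(/T), C, G.
#' @return The reverse-complement DNA string (uppercase).
#' @examples
#' reverse_complement_probe("CCCUAUCCCUUAUCUUAAC")  # "GTTAAGATAAGGGATAGGG"
#' @export
reverse_complement_probe <- function(rna_target) {
  s <- check_sequence(rna_target, what = "rna_target")
  s <- chartr("T", "U", s)
  rc <- Biostrings::reverseComplement(Biostrings::RNAString(s))
  as.character(Biostrings::DNAString(rc))
}

#' Reverse-complement a DNA probe back into its RNA target
#'
#' Inverse of [reverse_complement_probe()]: the round trip
#' target -> probe -> target is the identity.
#'
#' @param dna_probe DNA sequence over A, T(/U), G, C.
#' @return The reverse-complement RNA string (uppercase).
#' @export
reverse_complement_target <- function(dna_probe) {
  s <- check_sequence(dna_probe, what = "dna_probe")
  s <- chartr("U", "T", s)
  rc <- Biostrings::reverseComplement(Biostrings::DNAString(s))
  as.character(Biostrings::RNAString(rc))
}
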