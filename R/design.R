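#' Probe design configuration
#'
#' Bundles the tunable parameters of the probe/target design pipeline.
#'
#' @param k Oligo length (default 19).
#' @param gc_range Inclusive GC-fraction window, default `c(0.4, 0.6)`.
#' @param complexity_min Minimum LZ76 complexity retained (default 9, the
#'   level matched by typical exonic 19-mers).
#' @param n_samples Number of random draws (default 50000).
#' @param seed Optional integer seed for reproducible designs.
#' @param fold_energy_min Optional minimum self-folding free energy in
#'   kcal/mol; applied only to candidates annotated via
#'   [load_fold_energies()] (positive = unstructured).
#' @param target_alphabet Alphabet for RNA targets (default AUC).
#' @return Object of class `design_config`. The probe alphabet is implied:
#'   probes are reverse complements of the targets (AUC targets give ATG
#'   probes).
#' @export
design_config <- function(k = 19L, gc_range = c(0.4, 0.6),
                          complexity_min = 9L, n_samples = 50000L,
                          seed = NULL, fold_energy_min = NULL,
                          target_alphabet = alphabet_spec("AUC")) {
  k <- as.integer(k)
  n_samples <- as.integer(n_samples)
  stopifnot(k >= 1L, n_samples >= 1L, as.integer(complexity_min) >= 1L)
  gc_count_window(gc_range, k)  # validate achievability early
  structure(list(k = k, gc_range = gc_range,
                 complexity_min = as.integer(complexity_min),
                 n_samples = n_samples, seed = seed,
                 fold_energy_min = fold_energy_min,
                 target_alphabet = as_alphabet(target_alphabet)),
            class = "design_config")
}

#' Annotate oligo records with external fold energies
#'
#' Attaches self-folding free energies (e.g. computed by an external
#' nearest-neighbor folding tool at 37 degrees C) to matching oligo records.
#' The package never computes these energies itself.
#'
#' @param table Path to a two-column TSV (`sequence`, energy in kcal/mol,
#'   optional header) or an equivalent data frame.
#' @param oligos An [oligo_records()] data frame (or `kmer_sample`).
#' @return List with `oligos` (records with `fold_energy` filled in where
#'   matched) and `unmatched` (table sequences absent from the records).
#' @export
load_fold_energies <- function(table, oligos) {
  if (inherits(oligos, "kmer_sample")) oligos <- oligos$oligos
  stopifnot(is.data.frame(oligos), "sequence" %in% names(oligos))

  if (is.character(table)) {
    lines <- readLines(table)
    lines <- lines[nzchar(trimws(lines))]
    if (!length(lines))
      return(list(oligos = oligos, unmatched = character(0)))
    fields <- strsplit(lines, "\t", fixed = TRUE)
    start <- 1L
    if (length(fields[[1L]]) >= 2L &&
        is.na(suppressWarnings(as.numeric(fields[[1L]][2L]))))
      start <- 2L  # header row
    seqs <- character(0); energies <- numeric(0)
    for (i in seq(start, length.out = max(0L, length(lines) - start + 1L))) {
      f <- fields[[i]]
      val <- if (length(f) >= 2L) suppressWarnings(as.numeric(f[2L])) else NA
      if (length(f) < 2L || is.na(val))
        stop("malformed fold-energy row at line ", i, ": '", lines[i], "'")
      seqs <- c(seqs, toupper(trimws(f[1L]))); energies <- c(energies, val)
    }
    table <- data.frame(sequence = seqs, fold_energy = energies,
                        stringsAsFactors = FALSE)
  }
  stopifnot(is.data.frame(table), ncol(table) >= 2L)
  names(table)[1:2] <- c("sequence", "fold_energy")
  table$sequence <- toupper(table$sequence)

  if (anyDuplicated(table$sequence)) {
    dup <- unique(table$sequence[duplicated(table$sequence)])
    conflicting <- vapply(dup, function(s) {
      length(unique(table$fold_energy[table$sequence == s])) > 1L
    }, logical(1L))
    if (any(conflicting))
      stop("conflicting duplicate fold-energy rows for: ",
           paste(dup[conflicting], collapse = ", "))
    table <- table[!duplicated(table$sequence), , drop = FALSE]
  }

  idx <- match(oligos$sequence, table$sequence)
  oligos$fold_energy[!is.na(idx)] <- table$fold_energy[idx[!is.na(idx)]]
  list(oligos = oligos,
       unmatched = setdiff(table$sequence, oligos$sequence))
}

#' Design unstructured probe/target candidate pairs
#'
#' Samples random targets over the three-base target alphabet, applies the GC
#' and LZ76 complexity filters (and, if energies are annotated, a fold-energy
#' filter), and emits ranked (target, probe) pairs where the probe is the
#' reverse-complement DNA strand. Ranking is by complexity (descending), ties
#' broken by fold energy (descending, missing last) and then lexicographic
#' target order, so a fixed seed yields byte-identical output.
#'
#' @param config A [design_config()].
#' @param context Optional flanking sequence (e.g. the transcript around the
#'   insertion site). Candidates whose excess base-pairing with the context
#'   exceeds `max_context_pairs` are flagged `"context_structure"` as a
#'   warning that flanks may sequester the target.
#' @param fold_energies Optional fold-energy table (path or data frame)
#'   passed to [load_fold_energies()].
#' @param max_context_pairs Flagging threshold for context pairing
#'   (default 6 pairs).
#' @return Data frame with columns `target`, `probe`, `gc_fraction`,
#'   `g_count`, `lz_complexity`, `fold_energy`, `flags`; zero rows (with a
#'   message) when nothing survives the filters.
#' @export
design_probes <- function(config, context = NULL, fold_energies = NULL,
                          max_context_pairs = 6L) {
  stopifnot(inherits(config, "design_config"))
  sample <- generate_random_kmers(config$target_alphabet, k = config$k,
                                  n = config$n_samples,
                                  gc_range = config$gc_range,
                                  seed = config$seed)
  oligos <- sample$oligos
  if (!is.null(fold_energies))
    oligos <- load_fold_energies(fold_energies, oligos)$oligos

  oligos <- oligos[oligos$lz_complexity >= config$complexity_min, ,
                   drop = FALSE]
  if (!is.null(config$fold_energy_min)) {
    ok <- !is.na(oligos$fold_energy) &
      oligos$fold_energy >= config$fold_energy_min
    oligos <- oligos[ok, , drop = FALSE]
  }
  if (!nrow(oligos)) {
    message("no candidates survive the design filters")
    return(data.frame(target = character(0), probe = character(0),
                      gc_fraction = numeric(0), g_count = integer(0),
                      lz_complexity = integer(0), fold_energy = numeric(0),
                      flags = character(0), stringsAsFactors = FALSE))
  }

  ord <- order(-oligos$lz_complexity,
               -ifelse(is.na(oligos$fold_energy), -Inf, oligos$fold_energy),
               oligos$sequence)
  oligos <- oligos[ord, , drop = FALSE]

  flags <- rep("", nrow(oligos))
  if (!is.null(context)) {
    ctx <- check_sequence(context, what = "context")
    excess <- vapply(oligos$sequence, context_excess_pairs, integer(1L),
                     context = ctx)
    flags[excess > max_context_pairs] <- "context_structure"
  }

  data.frame(target = oligos$sequence,
             probe = vapply(oligos$sequence, reverse_complement_probe,
                            character(1L), USE.NAMES = FALSE),
             gc_fraction = oligos$gc_fraction,
             g_count = oligos$g_count,
             lz_complexity = oligos$lz_complexity,
             fold_energy = oligos$fold_energy,
             flags = flags,
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Write ranked candidates to TSV
#'
#' @param candidates A [design_probes()] result.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_candidates <- function(candidates, path) {
  write.table(candidates, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write oligo sequences as FASTA
#'
#' @param oligos An [oligo_records()] data frame, `kmer_sample`, or named
#'   character vector of sequences.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_oligos_fasta <- function(oligos, path) {
  if (inherits(oligos, "kmer_sample")) oligos <- oligos$oligos
  seqs <- if (is.data.frame(oligos)) oligos$sequence else oligos
  nm <- names(seqs) %||% paste0("oligo_", seq_along(seqs))
  set <- Biostrings::BStringSet(setNames(as.character(seqs), nm))
  Biostrings::writeXStringSet(set, path)
  invisible(path)
}
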