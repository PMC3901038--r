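test_that("LZ76 calibration strings and edge cases parse correctly", {
  expect_identical(lz_complexity("abcdefghijklmnopqrs"), 19L)
  expect_identical(lz_complexity(strrep("A", 19)), 2L)
  expect_identical(lz_complexity("ATATATATATATATATATA"), 3L)
  expect_identical(lz_complexity("A"), 1L)
  expect_error(lz_complexity(""), "non-empty")
})

test_that("LZ76 matches a brute-force definitional parser", {
  # exhaustively on all binary strings up to length 12
  for (L in 1:12) {
    ss <- do.call(paste0, expand.grid(rep(list(c("0", "1")), L),
                                      stringsAsFactors = FALSE))
    expect_identical(lz_complexity(ss),
                     vapply(ss, lz76_oracle, integer(1L), USE.NAMES = FALSE))
  }
  # and on random 19-mers over the design alphabets
  set.seed(101)
  for (letters in list(c("A", "U", "C"), c("A", "U", "G", "C"))) {
    x <- random_seqs(10000, 19, letters)
    expect_identical(lz_complexity(x),
                     vapply(x, lz76_oracle, integer(1L), USE.NAMES = FALSE))
  }
})

test_that("complexity values always lie in [1, length]", {
  set.seed(7)
  for (k in c(1, 2, 5, 19, 40)) {
    x <- random_seqs(200, k, c("A", "C", "G", "T"))
    cx <- lz_complexity(x)
    expect_true(all(cx >= 1 & cx <= k))
  }
})

test_that("random k-mer sampling respects the GC filter and is reproducible", {
  s1 <- generate_random_kmers("AUC", k = 19, n = 20000, seed = 11)
  s2 <- generate_random_kmers("AUC", k = 19, n = 20000, seed = 11)
  expect_identical(s1$oligos, s2$oligos)

  counts <- round(s1$oligos$gc_fraction * 19)
  expect_true(all(counts >= 8 & counts <= 11))
  # pure AUC: GC content is the C fraction
  c_counts <- vapply(s1$oligos$sequence, residue_count, integer(1L), "C")
  expect_identical(as.integer(counts), unname(c_counts))

  s3 <- generate_random_kmers("AUC", k = 19, n = 20000, seed = 12)
  expect_false(identical(s1$oligos$sequence[1:10], s3$oligos$sequence[1:10]))
})

test_that("four-letter GC yield matches the exact binomial sum", {
  # sum_{c=8..11} C(19,c) / 2^19 = 335920 / 524288
  expected <- sum(choose(19, 8:11)) / 2^19
  s <- generate_random_kmers("AUGC", k = 19, n = 50000, seed = 5)
  expect_equal(s$yield, expected, tolerance = 0.02)
})

test_that("unachievable gc_range errors and names the achievable window", {
  expect_error(generate_random_kmers("AUC", k = 19, n = 10,
                                     gc_range = c(0.98, 0.985)),
               "no integer GC count")
  # 19/19 = 1.0 is achievable, so [0.99, 1] is fine
  s <- generate_random_kmers("AUC", k = 19, n = 2000,
                             gc_range = c(0.99, 1), seed = 1)
  expect_true(all(s$oligos$sequence == strrep("C", 19) |
                    !nrow(s$oligos)))
})

test_that("mean complexity grows with alphabet size and is seed-stable", {
  s3a <- generate_random_kmers("AUC", 19, 50000, seed = 21)
  s3b <- generate_random_kmers("AUC", 19, 50000, seed = 22)
  s4 <- generate_random_kmers("AUGC", 19, 50000, seed = 21)
  m3a <- complexity_stats(s3a)$mean
  m3b <- complexity_stats(s3b)$mean
  m4 <- complexity_stats(s4)$mean
  expect_lt(m3a, m4)
  expect_lt(abs(m3a - m3b), 0.05)
})

test_that("complexity_stats summarizes exactly", {
  cs <- complexity_stats(c(7L, 8L, 8L, 9L, 10L), threshold = 9)
  expect_identical(cs$n, 5L)
  expect_equal(cs$mean, 8.4)
  expect_equal(sum(cs$histogram$probabilities), 1, tolerance = 1e-12)
  expect_equal(cs$fraction_at_or_above, 2 / 5)
  expect_error(complexity_stats(integer(0)), "empty")
})

test_that("residue counts and GC fractions match the printed probe pair", {
  f1_probe <- "GTTAAGATAAGGGATAGGG"
  expect_identical(residue_count(f1_probe, "G"), 8L)
  expect_equal(gc_fraction(f1_probe), 8 / 19)
  # three-base target region: no G at all
  expect_identical(residue_count("AACCACUCCAAUUACAUACACC", "G"), 0L)
  expect_identical(residue_count("AAAA", "C"), 0L)
  expect_error(residue_count("AXA", "A"), "invalid symbol")
  expect_error(gc_fraction("AB"), "invalid symbol")
})

test_that("reverse complement maps the printed F1 target to the F1 probe", {
  expect_identical(reverse_complement_probe("CCCUAUCCCUUAUCUUAAC"),
                   "GTTAAGATAAGGGATAGGG")
  expect_identical(reverse_complement_probe("AAA"), "TTT")
  set.seed(3)
  for (s in random_seqs(20, 19, c("A", "U", "C"))) {
    expect_identical(reverse_complement_target(reverse_complement_probe(s)),
                     s)
  }
  expect_error(reverse_complement_probe("AXC"), "invalid symbol")
})

test_that("tile_complexity slides a window over the sequence", {
  homo <- strrep("A", 25)
  expect_identical(tile_complexity(homo, 19), rep(2L, 7L))
  s <- "GTTAAGATAAGGGATAGGG"
  expect_identical(tile_complexity(s, 19), lz_complexity(s))
  expect_error(tile_complexity("ACGT", 19), "shorter than the window")
})

test_that("tile_complexity_fasta reads and concatenates records", {
  path <- withr::local_tempfile(fileext = ".fa")
  writeLines(c(">a", strrep("A", 15), ">b", strrep("A", 10)), path)
  expect_identical(tile_complexity_fasta(path, 19), rep(2L, 7L))
})

test_that("pairing proxy matches exhaustive enumeration and is RC-invariant", {
  expect_identical(pairing_proxy(strrep("A", 19)), 0L)
  expect_identical(pairing_proxy("GGGGAAAACCCC"), 4L)
  set.seed(17)
  for (L in 4:10) {
    for (s in random_seqs(40, L, c("A", "U", "G", "C"))) {
      expect_identical(pairing_proxy(s), nussinov_oracle(s))
      expect_identical(pairing_proxy(s, wobble = FALSE),
                       nussinov_oracle(s, wobble = FALSE))
    }
  }
  # Watson-Crick pairings map onto themselves under reverse complementation
  # (a G:U wobble maps to an unpairable C:A, so wobble scoring is excluded)
  for (s in random_seqs(50, 12, c("A", "U", "G", "C"))) {
    expect_identical(pairing_proxy(s, wobble = FALSE),
                     pairing_proxy(reverse_complement_probe(s),
                                   wobble = FALSE))
  }
})

test_that("fold-energy tables annotate matching records", {
  oligos <- oligo_records(c("CCCUAUCCCUUAUCUUAAC", "AAAAAAAAAAAAAAAAAAA"))
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("sequence\tdG", "CCCUAUCCCUUAUCUUAAC\t1.5",
               "UUUUUUUUUUUUUUUUUUU\t2.2"), path)
  res <- load_fold_energies(path, oligos)
  expect_equal(res$oligos$fold_energy[1L], 1.5)
  expect_true(is.na(res$oligos$fold_energy[2L]))
  expect_identical(res$unmatched, "UUUUUUUUUUUUUUUUUUU")

  # empty table: nothing changes
  empty <- withr::local_tempfile(fileext = ".tsv")
  writeLines(character(0), empty)
  expect_identical(load_fold_energies(empty, oligos)$oligos, oligos)

  # duplicate conflicting rows and malformed rows are errors
  bad <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("AAA\t1.0", "AAA\t2.0"), bad)
  expect_error(load_fold_energies(bad, oligos), "conflicting duplicate")
  mal <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("AAA\t1.0", "CCC\tnot_a_number"), mal)
  expect_error(load_fold_energies(mal, oligos), "line 2")
})

test_that("design_probes filters, ranks and emits complementary pairs", {
  cfg <- design_config(n_samples = 4000, seed = 33)
  out <- design_probes(cfg)
  expect_true(all(out$lz_complexity >= 9))
  expect_false(any(grepl("C", out$probe)))        # AUC target -> ATG probe
  expect_false(any(grepl("G", out$target)))
  expect_true(all(diff(out$lz_complexity) <= 0))  # ranked descending
  # ties broken lexicographically when no energies are loaded
  ties <- out$target[out$lz_complexity == out$lz_complexity[1L]]
  expect_identical(ties, sort(ties))
  # byte-identical under the same seed
  expect_identical(out, design_probes(cfg))
  # impossible filter: empty result with a message, not an error
  cfg2 <- design_config(n_samples = 50, complexity_min = 20, seed = 1)
  expect_message(res <- design_probes(cfg2), "no candidates")
  expect_identical(nrow(res), 0L)
})

test_that("design_probes flags targets sequestered by flanking context", {
  cfg <- design_config(n_samples = 500, seed = 8)
  ctx <- strrep("GGGAUGGGAUGGGAUGGGAU", 2)  # G-rich flank pairs with AUC
  out <- design_probes(cfg, context = ctx, max_context_pairs = 2)
  expect_true(any(out$flags == "context_structure"))
  # an all-C context cannot pair with G-free AUC targets
  out2 <- design_probes(cfg, context = strrep("C", 40))
  expect_true(all(out2$flags == ""))
})
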