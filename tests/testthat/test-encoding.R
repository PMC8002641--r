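test_that("sliding-window k-mer extraction follows the step-1 definition", {
  expect_equal(extract_kmers("ATGCA", 3), c("ATG", "TGC", "GCA"))
  expect_equal(extract_kmers("AAAA", 2), c("AA", "AA", "AA"))
  s200 <- random_dna(1, 200, seed = 3)
  km <- extract_kmers(s200, 2)
  # brute-force offset enumeration as the oracle
  oracle <- vapply(1:199, function(i) substr(s200, i, i + 1), character(1))
  expect_equal(length(km), 199L)
  expect_equal(km, oracle)
  expect_error(extract_kmers("AC", 3), "shorter than k")
})

test_that("reverse complement matches the Biostrings oracle", {
  seqs <- random_dna(20, 37, seed = 8)
  oracle <- as.character(Biostrings::reverseComplement(
    Biostrings::DNAStringSet(seqs)))
  expect_equal(reverse_complement(seqs), unname(oracle))
})

test_that("dictionary IDs follow order of appearance and skip bad k-mers", {
  d <- build_dictionary(records_df("ATGC"), 2, track_mode = "forward")
  expect_equal(d$entries, c(AT = 1L, TG = 2L, GC = 3L))
  d <- build_dictionary(records_df(c("AAAA", "AATT")), 2,
                        track_mode = "forward")
  expect_equal(d$entries, c(AA = 1L, AT = 2L, TT = 3L))
  # non-ACGT windows never enter the dictionary
  d <- build_dictionary(records_df("ANGC"), 2, track_mode = "forward")
  expect_equal(names(d$entries), "GC")
  # alphabet bound: a dataset containing every dinucleotide gives P = 16
  all16 <- paste(c(outer(c("A", "C", "G", "T"), c("A", "C", "G", "T"),
                         paste0)), collapse = "")
  d <- build_dictionary(records_df(all16), 2, track_mode = "forward")
  expect_equal(d$size, 16L)
  expect_setequal(d$entries, 1:16)
  # duplex mode scans the forward track first, then the RC track
  d <- build_dictionary(records_df("AAC"), 2, track_mode = "duplex")
  expect_equal(d$entries, c(AA = 1L, AC = 2L, GT = 3L, TT = 4L))
  expect_error(build_dictionary(records_df("NNNN"), 2), "no valid k-mer")
})

test_that("seeded dictionary variants are reproducible and well-formed", {
  recs <- records_df(random_dna(10, 30, seed = 4))
  shuf1 <- build_dictionary(recs, 2, "forward", shuffle = TRUE, seed = 7)
  shuf2 <- build_dictionary(recs, 2, "forward", shuffle = TRUE, seed = 7)
  base <- build_dictionary(recs, 2, "forward")
  expect_identical(shuf1$entries, shuf2$entries)
  expect_setequal(names(shuf1$entries), names(base$entries))
  expect_setequal(shuf1$entries, seq_len(shuf1$size))   # still 1..P
  sub <- build_dictionary(recs, 2, "forward", build_fraction = 0.5,
                          seed = 7)
  expect_lte(sub$size, base$size)
  expect_true(all(names(sub$entries) %in% names(base$entries)))
  expect_error(build_dictionary(recs, 2, "forward", build_fraction = 0.5),
               "seed")
})

test_that("encoding maps k-mers to IDs with 0 for misses", {
  d <- structure(list(k = 2L, entries = c(AT = 1L, TG = 2L, GC = 3L),
                      size = 3L, track_mode = "forward"),
                 class = "kmer_dictionary")
  expect_equal(encode("ATGC", d), c(1L, 2L, 3L))
  expect_equal(encode("ANGC", d), c(0L, 0L, 3L))
  # duplex feature count: 2 * (n - k + 1) = 398 for 200 bp, k = 2
  recs <- records_df(random_dna(3, 200, seed = 6))
  dict <- build_dictionary(recs, 2, "duplex")
  v <- encode(recs$sequence[1], dict, "duplex")
  expect_length(v, 398L)
  em <- encode_dataset(recs, dict, "duplex")
  expect_equal(dim(em$ids), c(3L, 398L))
})

test_that("encoded matrices respect order, determinism and edge cases", {
  recs <- records_df(random_dna(6, 30, seed = 10))
  dict <- build_dictionary(recs, 2, "duplex")
  em1 <- encode_dataset(recs, dict, labels = rep(0:1, 3))
  em2 <- encode_dataset(recs, dict, labels = rep(0:1, 3))
  expect_identical(em1$ids, em2$ids)
  # row order preserves record order
  expect_equal(em1$ids[2, ], encode(recs$sequence[2], dict))
  # training-set encoding never misses on any track
  expect_true(all(em1$ids >= 1L))
  # empty collection keeps the declared column count
  em0 <- encode_dataset(records_df(character(0), ids = character(0)),
                        dict, n = 30)
  expect_equal(dim(em0$ids), c(0L, 58L))
  expect_error(encode_dataset(records_df(c("ACGTACGT", "ACGT")), dict),
               "mixed sequence lengths")
  expect_error(encode_dataset(recs, dict, labels = 0:1), "labels length")
})

test_that("dictionary serialization is byte-stable and round-trips", {
  recs <- records_df(random_dna(5, 25, seed = 12))
  dict <- build_dictionary(recs, 2, "duplex")
  f1 <- withr::local_tempfile(); f2 <- withr::local_tempfile()
  write_dictionary(dict, f1)
  write_dictionary(build_dictionary(recs, 2, "duplex"), f2)
  expect_identical(readBin(f1, "raw", file.size(f1)),
                   readBin(f2, "raw", file.size(f2)))
  back <- read_dictionary(f1)
  expect_identical(back$entries, dict$entries)
  expect_equal(back$k, dict$k)
  expect_equal(back$size, dict$size)
  expect_equal(back$track_mode, dict$track_mode)
})
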