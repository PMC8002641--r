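test_that("generated class counts and shapes follow the configuration", {
  cfg <- synthetic_config(seed = 3)          # benchmark-shaped defaults
  ds <- generate_dataset(cfg)
  expect_equal(nrow(ds$records), 2968L)
  expect_equal(unname(ds$class_counts), c(742L, 742L, 1484L))
  expect_true(all(nchar(ds$records$sequence) == 200L))
})

test_that("generation is byte-reproducible and planting is optional", {
  cfg <- separable_synth_config(5, 5, 10, length = 30, seed = 4)
  d1 <- generate_dataset(cfg)
  d2 <- generate_dataset(cfg)
  expect_identical(d1$records, d2$records)
  f1 <- withr::local_tempfile(); f2 <- withr::local_tempfile()
  write_fasta(d1$records, f1); write_fasta(d2$records, f2)
  expect_identical(readBin(f1, "raw", file.size(f1)),
                   readBin(f2, "raw", file.size(f2)))
  # zero planting probability leaves pure background: identical to a
  # motif-free configuration under the same seed
  cfg0 <- cfg
  cfg0$motifs <- lapply(cfg0$motifs, function(m) {
    m$p_strong <- 0; m$p_weak <- 0; m$p_background <- 0; m
  })
  cfg_none <- cfg; cfg_none$motifs <- list()
  expect_identical(generate_dataset(cfg0)$records,
                   generate_dataset(cfg_none)$records)
  # motif overflow is rejected
  expect_error(synthetic_config(1, 1, 1, length = 10,
                                motifs = list(motif_spec("ACGTACGT", 5))),
               "overflows")
})

test_that("background base composition matches the configuration", {
  cfg <- synthetic_config(n_strong = 0, n_weak = 0, n_non = 500,
                          length = 200, motifs = list(),
                          base_composition = c(A = 0.4, C = 0.3, G = 0.2,
                                               T = 0.1), seed = 5)
  ds <- generate_dataset(cfg)
  bases <- strsplit(paste(ds$records$sequence, collapse = ""), "")[[1]]
  n <- length(bases)                          # 1e5 background bases
  counts <- table(bases)[c("A", "C", "G", "T")]
  # goodness of fit against the configured composition: at this n a real
  # bias in the generator drives the p-value to ~0
  gof <- chisq.test(counts, p = cfg$base_composition)
  expect_gt(gof$p.value, 1e-4)
  expect_true(all(abs(counts / n - cfg$base_composition) < 0.01))
})

test_that("planted_truth matches an independent sequence-masking oracle", {
  # forward track: motif span determines overlapping windows
  cfg <- synthetic_config(2, 2, 4, length = 30,
                          motifs = list(motif_spec("ACGT", 11L)), seed = 6)
  expect_equal(planted_truth(cfg, k = 2, track_mode = "forward"), 10:14)
  expect_equal(planted_truth(cfg, k = 3, track_mode = "forward"), 9:14)
  none <- cfg; none$motifs <- list()
  expect_equal(planted_truth(none, 2, "duplex"), integer(0))

  # oracle: encode a sequence, then the same sequence with the motif region
  # replaced by N; exactly the overlapping windows (on both tracks) change
  for (k in c(2L, 3L)) {
    set.seed(7)
    base <- random_dna(1, 30)
    masked <- base
    substr(masked, 11, 14) <- "NNNN"
    dict <- build_dictionary(records_df(random_dna(40, 30)), k, "duplex")
    v1 <- encode(base, dict, "duplex")
    v2 <- encode(masked, dict, "duplex")
    expect_equal(which(v2 == 0L), planted_truth(cfg, k, "duplex"))
    expect_true(all(v1[v2 == 0L] != 0L))
  }
})

test_that("selection recovery rises with the planted effect size", {
  base <- synthetic_config(n_strong = 15, n_weak = 15, n_non = 30,
                           length = 30,
                           motifs = list(motif_spec("ACGTAC", 11L,
                                                    p_background = 0.05)),
                           seed = 8)
  curve <- effect_size_curve(base, p_grid = c(0.05, 1.0), n_seeds = 5,
                             k = 2, track_mode = "forward")
  expect_equal(nrow(curve), 2L)
  # null point (planting probability equals background) is near chance
  expect_lt(abs(curve$recovery[1] - 0.5), 0.35)
  # strong planting is recovered far better than the null
  expect_gt(curve$recovery[2], curve$recovery[1])
  expect_gte(curve$recovery[2], 0.95)
})

test_that("ground-truth JSON records the planted columns", {
  cfg <- separable_synth_config(3, 3, 6, length = 30, seed = 9)
  f <- withr::local_tempfile(fileext = ".json")
  write_ground_truth(cfg, 2, "duplex", f)
  gt <- jsonlite::fromJSON(f)
  expect_equal(gt$planted_columns, planted_truth(cfg, 2, "duplex"))
  expect_equal(gt$n_strong, 3L)
  expect_equal(gt$seed, 9L)
})
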