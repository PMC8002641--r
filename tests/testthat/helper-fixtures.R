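# Shared fixtures: all synthetic, built in code at test time.

# a small network configuration that trains in well under a second
tiny_config <- function(...) {
  args <- modifyList(list(Q = 8L, lstm_size = 4L, dropout = 0.2,
                          batch_size = 16L, max_epochs = 2L, seed = 75L,
                          attention_size = 4L, learning_rate = 0.01),
                     list(...))
  do.call(model_config, args)
}

# records with hand-picked sequences
records_df <- function(sequences, ids = paste0("s", seq_along(sequences)),
                       label = NA_character_) {
  data.frame(id = ids, sequence = sequences,
             label = rep_len(label, length(sequences)),
             stringsAsFactors = FALSE)
}

random_dna <- function(n, len, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  vapply(seq_len(n), function(i) {
    paste(sample(c("A", "C", "G", "T"), len, replace = TRUE), collapse = "")
  }, character(1))
}

# a trivially separable encoded matrix: class-1 rows carry a distinctive ID
# run at fixed columns, class-0 rows a different one; IDs drawn over 1..P
separable_em <- function(n = 40L, t_cols = 12L, vocab = 6L, seed = 1L,
                         signal_cols = 3:6) {
  set.seed(seed)
  y <- rep(0:1, length.out = n)
  ids <- matrix(sample(seq_len(vocab), n * t_cols, replace = TRUE), n, t_cols)
  ids[y == 1L, signal_cols] <- 1L
  ids[y == 0L, signal_cols] <- 2L
  structure(list(ids = ids, labels = y, k = 2L, track_mode = "forward",
                 n = t_cols + 1L),
            class = "encoded_matrix")
}

# three-class analogue: one distinctive ID pattern per class
separable_em3 <- function(n = 48L, t_cols = 12L, vocab = 6L, seed = 1L) {
  set.seed(seed)
  y <- rep(0:2, length.out = n)
  ids <- matrix(sample(seq_len(vocab), n * t_cols, replace = TRUE), n, t_cols)
  for (cl in 0:2) ids[y == cl, 3:6] <- cl + 1L
  structure(list(ids = ids, labels = y, k = 2L, track_mode = "forward",
                 n = t_cols + 1L),
            class = "encoded_matrix")
}

# a small fully separable planted-motif dataset for end-to-end runs
separable_synth_config <- function(n_strong = 30L, n_weak = 30L,
                                   n_non = 60L, length = 40L, seed = 11L) {
  synthetic_config(
    n_strong = n_strong, n_weak = n_weak, n_non = n_non, length = length,
    motifs = list(motif_spec("ACGTACGT", c(5L, 21L),
                             p_strong = 1, p_weak = 1, p_background = 0)),
    seed = seed)
}

# independent chi-square oracle for one (column, labels) instance: builds
# the 2 x c contingency table from margins (classical textbook route) and
# returns per-category statistics and the summed upper-tail p-value
chi2_margin_oracle <- function(column, labels) {
  O <- table(factor(labels, levels = c(0, 1)), factor(column))
  E <- outer(rowSums(O), colSums(O)) / sum(O)
  cells <- (O - E)^2 / E
  stats <- colSums(cells)
  list(stats = unname(stats),
       position_pvalue = sum(pchisq(stats, df = 1, lower.tail = FALSE)))
}
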