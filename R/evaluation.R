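# Largest-remainder apportionment of a total across strata, proportional to
# counts; ties in the fractional parts resolved by stratum order.
apportion <- function(counts, total) {
  if (total == 0L || sum(counts) == 0L) return(integer(length(counts)))
  quota <- counts * total / sum(counts)
  base <- floor(quota)
  left <- total - sum(base)
  if (left > 0L) {
    extra <- order(quota - base, decreasing = TRUE)[seq_len(left)]
    base[extra] <- base[extra] + 1L
  }
  as.integer(base)
}

#' Stratified train/validation/test split
#'
#' The splitting protocol used throughout: a seeded stratified draw of 10%
#' of the samples as the test set, then 10% of the remainder as the
#' validation set, the rest as training data. Global sizes follow a floor
#' rule — `floor(0.1 n)` test, `floor(0.1 (n - test))` validation —
#' apportioned across classes by largest remainder so every split is
#' stratified and the totals are exact.
#'
#' @param labels Class label vector (any type) defining the strata.
#' @param seed Integer seed (default 75).
#' @param test_fraction Fraction for the test part (default 0.1; 0 for no
#'   test part).
#' @param val_fraction Fraction of the remainder for validation
#'   (default 0.1).
#' @return List of integer index vectors `train`, `validation`, `test`
#'   (pairwise disjoint, union = all indices).
#' @export
split_indices <- function(labels, seed = 75L, test_fraction = 0.1,
                          val_fraction = 0.1) {
  n <- length(labels)
  if (n < 10L && test_fraction > 0) {
    stop("dataset too small to split (n = ", n, ")", call. = FALSE)
  }
  old <- .Random.seed_save()
  set.seed(seed)
  strata <- split(seq_len(n), factor(labels, levels = unique(labels)))
  counts <- vapply(strata, length, integer(1))
  take_strat <- function(strata, quota) {
    picked <- vector("list", length(strata))
    for (s in seq_along(strata)) {
      picked[[s]] <- if (quota[s] > 0L) {
        sort(sample(strata[[s]], quota[s]))
      } else integer(0)
    }
    unlist(picked, use.names = FALSE)
  }
  test <- take_strat(strata, apportion(counts, floor(test_fraction * n)))
  remaining <- lapply(strata, setdiff, test)
  counts_r <- vapply(remaining, length, integer(1))
  validation <- take_strat(remaining,
                           apportion(counts_r,
                                     floor(val_fraction * sum(counts_r))))
  .Random.seed_restore(old)
  train <- setdiff(seq_len(n), c(test, validation))
  list(train = sort(train), validation = sort(validation),
       test = sort(test))
}

#' Split a benchmark dataset
#'
#' [split_indices()] applied to a `benchmark_dataset`, returning three
#' datasets.
#'
#' @param dataset A labelled `benchmark_dataset`.
#' @param seed Integer seed (default 75).
#' @param test_fraction,val_fraction See [split_indices()].
#' @return List of `benchmark_dataset`s: `train`, `validation`, `test`.
#' @export
split_protocol <- function(dataset, seed = 75L, test_fraction = 0.1,
                           val_fraction = 0.1) {
  idx <- split_indices(dataset$records$label, seed, test_fraction,
                       val_fraction)
  subset_ds <- function(rows) {
    records <- dataset$records[rows, , drop = FALSE]
    rownames(records) <- NULL
    counts <- vapply(label_levels, function(l) sum(records$label == l),
                     integer(1))
    structure(list(records = records,
                   expected_length = dataset$expected_length,
                   class_counts = counts, strict = dataset$strict),
              class = "benchmark_dataset")
  }
  lapply(idx, subset_ds)
}

# stratified fold assignment: within each class, samples are shuffled and
# dealt round-robin into folds
make_folds <- function(labels, n_folds, seed) {
  old <- .Random.seed_save()
  set.seed(seed)
  fold <- integer(length(labels))
  for (cl in unique(labels)) {
    idx <- sample(which(labels == cl))
    fold[idx] <- rep_len(seq_len(n_folds), length(idx))
  }
  .Random.seed_restore(old)
  fold
}

#' Leave-one-out cross-validation
#'
#' For each sample, trains a head on all remaining samples (with a
#' stratified 10% of them as the epoch-selection validation set) and
#' predicts the held-out sample; metrics are computed over all held-out
#' calls. Full-scale runs train one model per sample and are long-running;
#' `max_n` subsamples the dataset (stratified, seeded) for desk-scale use.
#'
#' @param em A labelled `encoded_matrix` (already masked).
#' @param config A [model_config()].
#' @param vocab_size Dictionary size P.
#' @param max_n Optional cap on the number of samples (stratified seeded
#'   subsample).
#' @return List with `report` (a `metrics_report`), `calls`, `probs`,
#'   `labels`.
#' @export
loocv <- function(em, config = model_config(), vocab_size, max_n = NULL) {
  y <- em$labels
  if (is.null(y)) stop("encoded matrix has no labels", call. = FALSE)
  rows <- seq_along(y)
  if (!is.null(max_n) && max_n < length(y)) {
    old <- .Random.seed_save()
    set.seed(config$seed)
    strata <- split(rows, y)
    quota <- apportion(vapply(strata, length, integer(1)),
                       as.integer(max_n))
    rows <- sort(unlist(mapply(function(ix, q) {
      if (q > 0L) sample(ix, q) else integer(0)
    }, strata, quota, SIMPLIFY = FALSE), use.names = FALSE))
    .Random.seed_restore(old)
  }
  if (length(rows) < 2L) stop("need at least 2 samples for LOOCV",
                              call. = FALSE)
  net <- build_network(config, ncol(em$ids), vocab_size, n_outputs = 1L)
  probs <- numeric(length(rows))
  for (j in seq_along(rows)) {
    i <- rows[j]
    rest <- setdiff(rows, i)
    yr <- y[rest]
    if (length(unique(yr)) < 2L) {
      stop("a LOOCV fold has single-class training labels", call. = FALSE)
    }
    idx <- split_indices(yr, seed = config$seed, test_fraction = 0,
                         val_fraction = 0.1)
    if (length(idx$validation) == 0L) {
      # at very small n the 10% floor is empty; hold out one sample per
      # class so epoch selection still has a validation signal
      move <- vapply(unique(yr), function(cl) {
        idx$train[match(cl, yr[idx$train])]
      }, integer(1))
      idx$validation <- move
      idx$train <- setdiff(idx$train, move)
    }
    tr <- subset_encoded(em, rest[idx$train])
    va <- subset_encoded(em, rest[idx$validation])
    head <- train_head(net, tr, va, config)
    probs[j] <- predict(head, subset_encoded(em, i))$prob
  }
  calls <- as.integer(probs >= config$threshold)
  labels <- y[rows]
  list(report = evaluate_predictions(labels, calls, probs),
       calls = calls, probs = probs, labels = labels)
}

#' Cross-validated hyperparameter grid search
#'
#' Exhaustive sweep over (`pLSTMSize`, `pDropoutRatio`, `pBatchSize`) with
#' stratified k-fold cross-validation (default 8 folds): each combination
#' is trained on each fold's complement (a stratified 10% of which is the
#' epoch-selection validation set) and evaluated on the held-out fold;
#' metrics are averaged over folds. The best row maximizes Acc, ties going
#' to the earlier grid row.
#'
#' @param em A labelled `encoded_matrix` (already masked).
#' @param vocab_size Dictionary size P.
#' @param lstm_sizes,dropouts,batch_sizes Grid value sets; defaults are the
#'   full tuning grid (3 x 7 x 6 = 126 combinations). Restrict them for
#'   desk-scale runs.
#' @param folds Number of cross-validation folds (default 8).
#' @param config Base [model_config()] supplying all other settings.
#' @return A `grid_result`: list with `rows` (data.frame: pLSTMSize,
#'   pDropoutRatio, pBatchSize, Sn, Sp, Acc, MCC, AUC) and `best` (the
#'   argmax-Acc row).
#' @export
grid_search <- function(em, vocab_size,
                        lstm_sizes = c(64L, 128L, 192L),
                        dropouts = seq(0.1, 0.7, by = 0.1),
                        batch_sizes = c(16L, 32L, 64L, 128L, 256L, 512L),
                        folds = 8L, config = model_config()) {
  y <- em$labels
  fold <- make_folds(y, folds, config$seed)
  grid <- expand.grid(pBatchSize = batch_sizes, pDropoutRatio = dropouts,
                      pLSTMSize = lstm_sizes)[, 3:1]
  rows <- vector("list", nrow(grid))
  for (gi in seq_len(nrow(grid))) {
    cfg <- config
    cfg$lstm_size <- grid$pLSTMSize[gi]
    cfg$dropout <- grid$pDropoutRatio[gi]
    cfg$batch_size <- grid$pBatchSize[gi]
    net <- build_network(cfg, ncol(em$ids), vocab_size, n_outputs = 1L)
    ms <- vector("list", folds)
    for (f in seq_len(folds)) {
      hold <- which(fold == f)
      rest <- which(fold != f)
      idx <- split_indices(y[rest], seed = cfg$seed, test_fraction = 0,
                           val_fraction = 0.1)
      head <- train_head(net, subset_encoded(em, rest[idx$train]),
                         subset_encoded(em, rest[idx$validation]), cfg)
      pr <- predict(head, subset_encoded(em, hold))
      ms[[f]] <- evaluate_predictions(y[hold], pr$call, pr$prob)
    }
    avg <- function(nm) mean(vapply(ms, function(m) m[[nm]], numeric(1)))
    rows[[gi]] <- data.frame(pLSTMSize = grid$pLSTMSize[gi],
                             pDropoutRatio = grid$pDropoutRatio[gi],
                             pBatchSize = grid$pBatchSize[gi],
                             Sn = avg("Sn"), Sp = avg("Sp"), Acc = avg("Acc"),
                             MCC = avg("MCC"), AUC = avg("AUC"))
  }
  rows <- do.call(rbind, rows)
  structure(list(rows = rows, best = rows[which.max(rows$Acc), ]),
            class = "grid_result")
}

#' @export
print.grid_result <- function(x, ...) {
  cat("grid_result:", nrow(x$rows), "combinations; best:\n")
  print(x$best, row.names = FALSE)
  invisible(x)
}

#' Word-vector-dimension sweep
#'
#' Trains and evaluates one head per embedding dimension; the default
#' dimension set is the eight evaluated values 12, 24, 48, 96, 192, 394,
#' 768, 1536.
#'
#' @param train,val,test Labelled `encoded_matrix` objects (already
#'   masked).
#' @param vocab_size Dictionary size P.
#' @param dims Embedding dimensions to evaluate.
#' @param config Base [model_config()].
#' @return Data.frame with columns `Q`, `Sn`, `Sp`, `Acc`, `MCC`, `AUC`.
#' @export
qsweep <- function(train, val, test, vocab_size,
                   dims = c(12L, 24L, 48L, 96L, 192L, 394L, 768L, 1536L),
                   config = model_config()) {
  rows <- lapply(dims, function(q) {
    cfg <- config
    cfg$Q <- as.integer(q)
    net <- build_network(cfg, ncol(train$ids), vocab_size, n_outputs = 1L)
    head <- train_head(net, train, val, cfg)
    pr <- predict(head, test)
    m <- evaluate_predictions(test$labels, pr$call, pr$prob)
    data.frame(Q = q, Sn = m$Sn, Sp = m$Sp, Acc = m$Acc, MCC = m$MCC,
               AUC = m$AUC)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Write a metrics table as TSV
#'
#' Generic exporter for grid/sweep/metric tables in the
#' `Acc Sn Sp MCC AUC` column layout (parameter columns first).
#'
#' @param table A data.frame (e.g. `grid_result$rows`, [qsweep()] output).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_metrics_table <- function(table, path) {
  write.table(table, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}
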