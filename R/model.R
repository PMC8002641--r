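#' Train the full two-layer enhancer model
#'
#' End-to-end model construction from a labelled training dataset: builds
#' the k-mer dictionary from the training sequences, encodes them, scores
#' and removes the K most uninformative positions, then trains the two
#' cascade heads — detection (enhancer vs non-enhancer, on all records) and
#' strength (strong vs weak, on enhancers only) — with the same
#' architecture and protocol. Validation data for epoch selection is split
#' off the training records per [split_indices()].
#'
#' @param dataset A labelled `benchmark_dataset` (training data).
#' @param k Word length (default 2).
#' @param track_mode `"duplex"` (default) or `"forward"`.
#' @param K_removed Positions removed by the chi-squared screen
#'   (default 45).
#' @param config A [model_config()].
#' @param val_fraction Fraction of records held out (stratified) for
#'   epoch selection (default 0.1).
#' @return An `spenhancer_model`: list with `detection`, `strength`
#'   (`trained_head`s), `dictionary`, `score_table`, `mask`, `k`,
#'   `track_mode`, `config`.
#' @export
train_two_layer <- function(dataset, k = 2L,
                            track_mode = c("duplex", "forward"),
                            K_removed = 45L, config = model_config(),
                            val_fraction = 0.1) {
  track_mode <- match.arg(track_mode)
  records <- dataset$records
  dict <- build_dictionary(records, k, track_mode)
  # detection task: all records
  det <- binary_view(dataset, "detection")
  em_det <- encode_dataset(det$records, dict, track_mode,
                           labels = det$labels, strict = dataset$strict)
  score <- score_all_positions(em_det)
  score <- remove_top_k(score, K_removed)
  em_det <- apply_mask(em_det, score)
  heads <- list()
  for (layer in c("detection", "strength")) {
    view <- binary_view(dataset, layer)
    em <- encode_dataset(view$records, dict, track_mode,
                         labels = view$labels, strict = dataset$strict)
    em <- apply_mask(em, score)
    idx <- split_indices(view$labels, seed = config$seed,
                         test_fraction = 0, val_fraction = val_fraction)
    tr <- subset_encoded(em, idx$train)
    va <- subset_encoded(em, idx$validation)
    net <- build_network(config, ncol(em$ids), dict$size, n_outputs = 1L)
    heads[[layer]] <- train_head(net, tr, va, config, role = layer)
  }
  structure(list(detection = heads$detection, strength = heads$strength,
                 dictionary = dict, score_table = score,
                 mask = score$removed, k = dict$k, track_mode = track_mode,
                 config = config),
            class = "spenhancer_model")
}

#' @export
print.spenhancer_model <- function(x, ...) {
  cat("spenhancer_model: k =", x$k, "(", x$track_mode, "),",
      sum(x$mask), "positions removed,", sum(!x$mask), "kept\n")
  print(x$detection); print(x$strength)
  invisible(x)
}

subset_encoded <- function(em, rows) {
  em$ids <- em$ids[rows, , drop = FALSE]
  if (!is.null(em$labels)) em$labels <- em$labels[rows]
  em
}

#' Two-layer cascade prediction
#'
#' Applies the gating rule of the cascade: a record called negative by the
#' detection head is a non-enhancer and the strength head is never
#' consulted for its category; a detected enhancer is strong if the
#' strength head calls 1, weak otherwise.
#'
#' @param model An `spenhancer_model`.
#' @param records Record data.frame (or `benchmark_dataset`) of query
#'   sequences.
#' @return Data.frame with `id`, `prob_layer1`, `prob_layer2`, `category`.
#'   `prob_layer2` is reported for all records but only determines the
#'   category of detected enhancers.
#' @export
predict_two_layer <- function(model, records) {
  if (inherits(records, "benchmark_dataset")) records <- records$records
  em <- encode_dataset(records, model$dictionary, model$track_mode,
                       strict = FALSE)
  em <- apply_mask(em, model$mask)
  p1 <- predict(model$detection, em)
  p2 <- predict(model$strength, em)
  category <- ifelse(p1$call == 0L, "non_enhancer",
                     ifelse(p2$call == 1L, "strong_enhancer",
                            "weak_enhancer"))
  data.frame(id = records$id,
             prob_layer1 = p1$prob,
             prob_layer2 = p2$prob,
             category = category,
             stringsAsFactors = FALSE)
}

#' Save a model bundle
#'
#' Writes a directory with the weight container (`weights.rds`), a
#' `manifest.json` recording every hyperparameter and provenance field, the
#' dictionary TSV and the removal-mask JSON.
#'
#' @param model An `spenhancer_model`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
save_model <- function(model, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  saveRDS(list(detection = model$detection, strength = model$strength),
          file.path(dir, "weights.rds"))
  cfg <- model$config
  manifest <- list(Q = cfg$Q, pLSTMSize = cfg$lstm_size,
                   pDropoutRatio = cfg$dropout, pBatchSize = cfg$batch_size,
                   max_epochs = cfg$max_epochs, seed = cfg$seed,
                   threshold = cfg$threshold, k = model$k,
                   track_mode = model$track_mode,
                   P = model$dictionary$size, K = sum(model$mask),
                   input_columns = model$detection$input_columns,
                   roles = c("detection", "strength"),
                   reconstructed = c("attention_form", "loss", "adam_details",
                                     "embedding_init"))
  writeLines(jsonlite::toJSON(manifest, auto_unbox = TRUE, digits = NA),
             file.path(dir, "manifest.json"))
  write_dictionary(model$dictionary, file.path(dir, "dictionary.tsv"))
  write_mask(model$score_table, file.path(dir, "mask.json"))
  invisible(dir)
}

#' Load a model bundle
#'
#' @param dir Directory written by [save_model()].
#' @return An `spenhancer_model`.
#' @export
load_model <- function(dir) {
  for (f in c("weights.rds", "manifest.json", "dictionary.tsv", "mask.json")) {
    if (!file.exists(file.path(dir, f))) {
      stop("model bundle is missing component: ", f, call. = FALSE)
    }
  }
  heads <- readRDS(file.path(dir, "weights.rds"))
  manifest <- jsonlite::fromJSON(file.path(dir, "manifest.json"))
  dict <- read_dictionary(file.path(dir, "dictionary.tsv"))
  mask <- read_mask(file.path(dir, "mask.json"))
  score <- structure(list(position_pvalues = NULL, ranking = NULL,
                          removed = as.logical(mask), K = attr(mask, "K"),
                          n_columns = attr(mask, "n_columns"),
                          k = manifest$k, track_mode = manifest$track_mode),
                     class = "position_score_table")
  structure(list(detection = heads$detection, strength = heads$strength,
                 dictionary = dict, score_table = score,
                 mask = as.logical(mask), k = manifest$k,
                 track_mode = manifest$track_mode,
                 config = heads$detection$config),
            class = "spenhancer_model")
}

#' Write cascade predictions as TSV
#'
#' Columns: `id`, `prob_layer1`, `prob_layer2`, `category`.
#'
#' @param predictions Data.frame from [predict_two_layer()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_predictions <- function(predictions, path) {
  write.table(predictions, path, sep = "\t", row.names = FALSE,
              quote = FALSE)
  invisible(path)
}
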