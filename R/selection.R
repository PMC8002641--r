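#' One-hot expansion of a single position column
#'
#' Expands one column of the encoded matrix into an indicator matrix over
#' the k-mer categories present at that position (ascending ID order), and
#' the 0/1 label vector into a two-column class indicator (class 0 first).
#' These are the working quantities of the per-position chi-squared screen.
#'
#' @param column Integer ID vector for one position.
#' @param labels 0/1 label vector of the same length; both classes must be
#'   present.
#' @return A `chi2_work` list: `X` (samples x categories indicator),
#'   `Y` (samples x 2 class indicator), `categories` (ID values),
#'   `vFeatureSum` (per-category totals), `vProbClass` (class proportions,
#'   class 0 then class 1), `N`, `N0`, `N1`.
#' @export
onehot_expand <- function(column, labels) {
  if (length(column) != length(labels) || length(column) < 1L) {
    stop("column and labels must have equal positive length", call. = FALSE)
  }
  n1 <- sum(labels == 1L)
  n0 <- sum(labels == 0L)
  if (n1 == 0L || n0 == 0L) {
    stop("labels must contain both classes", call. = FALSE)
  }
  categories <- sort(unique(column))
  X <- outer(column, categories, `==`) * 1
  colnames(X) <- as.character(categories)
  Y <- cbind(`0` = as.numeric(labels == 0L), `1` = as.numeric(labels == 1L))
  structure(list(X = X, Y = Y, categories = categories,
                 vFeatureSum = colSums(X),
                 vProbClass = c(n0, n1) / length(labels),
                 N = length(labels), N0 = n0, N1 = n1),
            class = "chi2_work")
}

#' Per-position chi-squared statistics and summed p-value
#'
#' From the one-hot work matrices, forms the observed class-by-category
#' count table as the cross-product of the class and category indicators,
#' the expected table as the outer product of the class proportions with the
#' per-category totals, and the per-cell statistic (observed - expected)^2 /
#' expected. Each category's statistic is the sum of its class cells; its
#' p-value is the chi-square upper tail at df = (classes - 1). The
#' position's score is the *sum* of the category p-values — a ranking score
#' for uninformativeness (it can exceed 1), not a probability.
#'
#' @param work A `chi2_work` from [onehot_expand()].
#' @return List with `vObserved`, `vExpected` (classes x categories),
#'   `chi2_cells`, `category_stats`, `category_pvalues`, `position_pvalue`.
#' @export
chi2_position <- function(work) {
  vObserved <- t(work$Y) %*% work$X
  vExpected <- outer(work$vProbClass, work$vFeatureSum)
  dimnames(vExpected) <- dimnames(vObserved)
  if (any(vExpected == 0)) {
    stop("zero expected cell (a class has zero samples)", call. = FALSE)
  }
  cells <- (vObserved - vExpected)^2 / vExpected
  stats <- colSums(cells)
  pvals <- pchisq(stats, df = nrow(vObserved) - 1L, lower.tail = FALSE)
  list(vObserved = vObserved, vExpected = vExpected, chi2_cells = cells,
       category_stats = stats, category_pvalues = pvals,
       position_pvalue = sum(pvals))
}

#' Score every position of an encoded matrix
#'
#' Runs the chi-squared screen over all columns and ranks positions by their
#' summed p-value in descending order (large = uninformative = removable),
#' ties broken by ascending column index.
#'
#' @param em An `encoded_matrix` with 0/1 labels covering both classes.
#' @return A `position_score_table`: list with `position_pvalues`, `ranking`
#'   (column indices, most-removable first), `removed` (logical mask,
#'   initially all `FALSE`), `K` (0), `n_columns`, `k`, `track_mode`.
#' @export
score_all_positions <- function(em) {
  labels <- em$labels
  if (is.null(labels)) stop("encoded matrix has no labels", call. = FALSE)
  n1 <- sum(labels == 1L); n0 <- sum(labels == 0L)
  if (n1 == 0L || n0 == 0L) stop("labels must contain both classes",
                                 call. = FALSE)
  n <- length(labels)
  prob <- c(n0, n1) / n
  lab1 <- labels == 1L
  pvalues <- vapply(seq_len(ncol(em$ids)), function(j) {
    col <- em$ids[, j]
    # per-category observed counts by class; same arithmetic as the one-hot
    # matrix route, computed sparsely
    tot <- table(col)
    obs1 <- table(factor(col[lab1], levels = names(tot)))
    obs0 <- as.numeric(tot) - as.numeric(obs1)
    e0 <- prob[1] * as.numeric(tot)
    e1 <- prob[2] * as.numeric(tot)
    stat <- (obs0 - e0)^2 / e0 + (as.numeric(obs1) - e1)^2 / e1
    sum(pchisq(stat, df = 1, lower.tail = FALSE))
  }, numeric(1))
  structure(list(position_pvalues = pvalues,
                 ranking = order(pvalues, decreasing = TRUE),
                 removed = rep(FALSE, length(pvalues)),
                 K = 0L,
                 n_columns = ncol(em$ids),
                 k = em$k, track_mode = em$track_mode),
            class = "position_score_table")
}

#' @export
print.position_score_table <- function(x, ...) {
  cat("position_score_table:", x$n_columns, "positions,", x$K, "removed\n")
  invisible(x)
}

#' Mark the K most uninformative positions for removal
#'
#' @param table A `position_score_table`.
#' @param K Number of positions to remove (default 45); must satisfy
#'   `0 <= K < n_columns`. Ties in the summed p-value are broken by removing
#'   the lower column index first.
#' @return The table with `removed` set at the K largest summed p-values and
#'   `K` updated.
#' @export
remove_top_k <- function(table, K = 45L) {
  K <- as.integer(K)
  if (K < 0L || K >= table$n_columns) {
    stop("K must satisfy 0 <= K < ", table$n_columns, " (got ", K, ")",
         call. = FALSE)
  }
  removed <- rep(FALSE, table$n_columns)
  # order() is stable: equal p-values keep ascending column order
  removed[table$ranking[seq_len(K)]] <- TRUE
  table$removed <- removed
  table$K <- K
  table
}

#' Apply a removal mask to an encoded matrix
#'
#' Drops the masked columns. The same mask must be applied to every matrix
#' in a study (train and test alike) so surviving positions stay aligned.
#'
#' @param em An `encoded_matrix`.
#' @param mask Logical vector (`TRUE` = remove) of length `ncol(em$ids)`,
#'   or a `position_score_table` whose `removed` mask is used.
#' @return The masked `encoded_matrix` with a `kept_columns` field recording
#'   the surviving original indices.
#' @export
apply_mask <- function(em, mask) {
  if (inherits(mask, "position_score_table")) mask <- mask$removed
  if (length(mask) != ncol(em$ids)) {
    stop("mask length (", length(mask), ") != column count (",
         ncol(em$ids), ")", call. = FALSE)
  }
  em$kept_columns <- which(!mask)
  em$ids <- em$ids[, !mask, drop = FALSE]
  em
}

#' Performance-vs-removal sweep
#'
#' Reproduces the two-stage removal protocol: a coarse pass removing
#' positions in steps of `coarse_step` up to `coarse_max`, then a fine pass
#' of single-position steps beyond the pivot.
#'
#' @param table A `position_score_table`.
#' @param evaluator Function taking a removal mask and returning a named
#'   list/vector with `Sn`, `Sp`, `Acc`, `MCC`, `AUC`.
#' @param coarse_step Coarse step size (default 5).
#' @param coarse_max Largest coarse K (default 45).
#' @param fine_steps Number of single steps past the pivot (default 5).
#' @param pivot Start of the fine pass (default `coarse_max`).
#' @return Data.frame with columns `K`, `stage`, `Sn`, `Sp`, `Acc`, `MCC`,
#'   `AUC`.
#' @export
removal_sweep <- function(table, evaluator, coarse_step = 5L,
                          coarse_max = 45L, fine_steps = 5L,
                          pivot = coarse_max) {
  ks <- c(seq(0L, coarse_max, by = coarse_step),
          if (fine_steps > 0L) pivot + seq_len(fine_steps))
  stage <- c(rep("coarse", length(seq(0L, coarse_max, by = coarse_step))),
             rep("fine", fine_steps))
  rows <- lapply(ks, function(K) {
    m <- remove_top_k(table, K)
    res <- evaluator(m$removed)
    data.frame(K = K, Sn = res[["Sn"]], Sp = res[["Sp"]], Acc = res[["Acc"]],
               MCC = res[["MCC"]], AUC = res[["AUC"]])
  })
  out <- do.call(rbind, rows)
  out <- cbind(K = out$K, stage = stage, out[, -1, drop = FALSE])
  rownames(out) <- NULL
  out
}

#' Export the position score table as TSV
#'
#' Columns: `position`, `pvalue`, `rank` (1 = most removable), `removed`.
#'
#' @param table A `position_score_table`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_score_table <- function(table, path) {
  rank <- integer(table$n_columns)
  rank[table$ranking] <- seq_len(table$n_columns)
  out <- data.frame(position = seq_len(table$n_columns),
                    pvalue = table$position_pvalues,
                    rank = rank,
                    removed = table$removed)
  write.table(out, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Serialize a removal mask to JSON
#'
#' A JSON object with the removed column indices (1-based) and the mask
#' provenance (`K`, `n_columns`, `k`, `track_mode`). Byte-stable.
#'
#' @param table A `position_score_table` (after [remove_top_k()]).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_mask <- function(table, path) {
  obj <- list(removed_columns = which(table$removed),
              K = table$K, n_columns = table$n_columns,
              k = table$k, track_mode = table$track_mode)
  writeLines(jsonlite::toJSON(obj, auto_unbox = TRUE, digits = NA), path)
  invisible(path)
}

#' Read a serialized removal mask
#'
#' @param path Path written by [write_mask()].
#' @return Logical removal mask with attributes `K`, `n_columns`.
#' @export
read_mask <- function(path) {
  obj <- jsonlite::fromJSON(path)
  mask <- rep(FALSE, obj$n_columns)
  mask[obj$removed_columns] <- TRUE
  attr(mask, "K") <- obj$K
  attr(mask, "n_columns") <- obj$n_columns
  mask
}
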