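#' @importFrom stats pchisq runif setNames predict sd
#' @importFrom utils write.table read.table head modifyList packageVersion
NULL

#' Enhancer class labels
#'
#' The three sequence categories handled by the package, in canonical order:
#' strong enhancer, weak enhancer, non-enhancer.
#'
#' @export
label_levels <- c("strong_enhancer", "weak_enhancer", "non_enhancer")

validate_labels <- function(label) {
  bad <- !is.na(label) & !(label %in% label_levels)
  if (any(bad)) {
    stop("unknown label(s): ", paste(unique(label[bad]), collapse = ", "),
         " (expected one of: ", paste(label_levels, collapse = ", "), ")",
         call. = FALSE)
  }
  invisible(label)
}

#' Read a FASTA file of fixed-length sequences
#'
#' Reads every entry of a FASTA file into a record table. Sequences are
#' uppercased; characters outside A/C/G/T are kept as-is (downstream k-mer
#' stages treat any window containing them as out-of-dictionary).
#'
#' @param path Path to a FASTA file.
#' @param label Optional class label (one of [label_levels]) attached to
#'   every record, for per-class benchmark files.
#' @return A data.frame with columns `id`, `sequence` and `label`
#'   (`NA` when no label is supplied).
#' @export
read_fasta <- function(path, label = NULL) {
  if (!file.exists(path)) stop("FASTA file not found: ", path, call. = FALSE)
  set <- tryCatch(
    Biostrings::readBStringSet(path),
    error = function(e) stop("malformed FASTA in ", path, ": ",
                             conditionMessage(e), call. = FALSE)
  )
  if (length(set) == 0L) stop("empty FASTA file: ", path, call. = FALSE)
  lab <- if (is.null(label)) NA_character_ else validate_labels(label)
  # FASTA headers may carry descriptions after whitespace; the id is the
  # first token, as samtools/Biostrings conventions define it.
  ids <- sub("\\s.*$", "", names(set))
  data.frame(id = ids,
             sequence = toupper(as.character(set)),
             label = rep(lab, length(set)),
             stringsAsFactors = FALSE)
}

#' Write records to FASTA
#'
#' @param records A record data.frame (`id`, `sequence`).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(records, path) {
  set <- Biostrings::BStringSet(records$sequence)
  names(set) <- records$id
  Biostrings::writeXStringSet(set, path)
  invisible(path)
}

#' Read a two-column label table
#'
#' Reads an `id<TAB>label` TSV (header optional; detected by the second
#' field of the first line not being a known label).
#'
#' @param path Path to the TSV.
#' @return A data.frame with columns `id`, `label`.
#' @export
read_label_tsv <- function(path) {
  tab <- read.table(path, sep = "\t", header = FALSE,
                    stringsAsFactors = FALSE, col.names = c("id", "label"))
  if (nrow(tab) > 0 && !(tab$label[1] %in% label_levels)) {
    tab <- tab[-1, , drop = FALSE]   # header row
  }
  validate_labels(tab$label)
  rownames(tab) <- NULL
  tab
}

#' Attach labels from a label table to records
#'
#' @param records Record data.frame.
#' @param labels Data.frame from [read_label_tsv()].
#' @return Records with the `label` column filled by id lookup.
#' @export
attach_labels <- function(records, labels) {
  idx <- match(records$id, labels$id)
  if (anyNA(idx)) {
    stop("no label for record id(s): ",
         paste(head(records$id[is.na(idx)], 5), collapse = ", "),
         call. = FALSE)
  }
  records$label <- labels$label[idx]
  records
}

#' Assemble a labelled benchmark dataset
#'
#' Combines per-class record collections into a single dataset in the stable
#' order strong, weak, non-enhancer, and validates sequence lengths.
#'
#' @param strong,weak,non Record data.frames for the three classes. Labels
#'   are attached (and checked for consistency when already present).
#' @param expected_length Expected sequence length in bp (default 200).
#' @param strict When `TRUE` (default), every sequence must have exactly
#'   `expected_length` bases.
#' @return A `benchmark_dataset`: list with `records`, `expected_length`,
#'   `class_counts` and `strict`.
#' @export
assemble_dataset <- function(strong, weak, non, expected_length = 200L,
                             strict = TRUE) {
  fix <- function(records, lab) {
    if (is.null(records) || nrow(records) == 0L) {
      return(data.frame(id = character(), sequence = character(),
                        label = character(), stringsAsFactors = FALSE))
    }
    if (!is.null(records$label) && any(!is.na(records$label) &
                                       records$label != lab)) {
      stop("records passed as ", lab, " carry a different label",
           call. = FALSE)
    }
    records$label <- lab
    records[, c("id", "sequence", "label")]
  }
  records <- rbind(fix(strong, "strong_enhancer"),
                   fix(weak, "weak_enhancer"),
                   fix(non, "non_enhancer"))
  rownames(records) <- NULL
  if (strict && nrow(records) > 0L) {
    len <- nchar(records$sequence)
    if (any(len != expected_length)) {
      stop("sequence length != ", expected_length, " for record(s): ",
           paste(head(records$id[len != expected_length], 5), collapse = ", "),
           call. = FALSE)
    }
  }
  counts <- vapply(label_levels, function(l) sum(records$label == l),
                   integer(1))
  structure(list(records = records,
                 expected_length = as.integer(expected_length),
                 class_counts = counts,
                 strict = strict),
            class = "benchmark_dataset")
}

#' @export
print.benchmark_dataset <- function(x, ...) {
  cat("benchmark_dataset:", nrow(x$records), "sequences of",
      x$expected_length, "bp\n")
  for (l in label_levels) cat("  ", l, ": ", x$class_counts[[l]], "\n", sep = "")
  invisible(x)
}

#' Binary view of a benchmark dataset
#'
#' Projects the three-class dataset onto one of the two cascade tasks:
#' `detection` keeps all records and labels enhancers (strong or weak) 1,
#' non-enhancers 0; `strength` keeps only enhancers and labels strong 1,
#' weak 0.
#'
#' @param dataset A `benchmark_dataset`.
#' @param layer `"detection"` or `"strength"`.
#' @return List with `records` (data.frame) and `labels` (0/1 integer
#'   vector).
#' @export
binary_view <- function(dataset, layer = c("detection", "strength")) {
  layer <- match.arg(layer)
  records <- dataset$records
  if (anyNA(records$label)) stop("dataset contains unlabelled records",
                                 call. = FALSE)
  if (layer == "detection") {
    labels <- as.integer(records$label != "non_enhancer")
  } else {
    keep <- records$label != "non_enhancer"
    records <- records[keep, , drop = FALSE]
    rownames(records) <- NULL
    labels <- as.integer(records$label == "strong_enhancer")
  }
  list(records = records, labels = labels)
}
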