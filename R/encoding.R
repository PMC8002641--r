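#' Extract step-1 sliding-window k-mers
#'
#' @param sequence A single sequence string.
#' @param k Word length (>= 1).
#' @return Character vector of the `nchar(sequence) - k + 1` k-mers, the
#'   i-th starting at position i.
#' @export
extract_kmers <- function(sequence, k) {
  n <- nchar(sequence)
  k <- as.integer(k)
  if (k < 1L) stop("k must be >= 1", call. = FALSE)
  if (n < k) stop("sequence of length ", n, " is shorter than k = ", k,
                  call. = FALSE)
  starts <- seq_len(n - k + 1L)
  substring(sequence, starts, starts + k - 1L)
}

#' Reverse complement of a DNA string
#'
#' A<->T and C<->G with sequence reversal. Characters outside A/C/G/T are
#' left unchanged (and still reversed in position); k-mers containing them
#' never enter the dictionary.
#'
#' @param sequence Sequence string (uppercase).
#' @return The reverse-complement string.
#' @export
reverse_complement <- function(sequence) {
  comp <- chartr("ACGT", "TGCA", sequence)
  vapply(comp, function(s) {
    paste(rev(strsplit(s, "", fixed = TRUE)[[1]]), collapse = "")
  }, character(1), USE.NAMES = FALSE)
}

is_valid_kmer <- function(kmers) grepl("^[ACGT]+$", kmers)

record_kmer_stream <- function(sequences, k, track_mode) {
  streams <- lapply(sequences, function(s) {
    fw <- extract_kmers(s, k)
    if (track_mode == "duplex") c(fw, extract_kmers(reverse_complement(s), k))
    else fw
  })
  unlist(streams, use.names = FALSE)
}

#' Build a k-mer dictionary from training sequences
#'
#' Assigns each distinct k-mer observed in the training records a positive
#' integer ID. The default rule is deterministic order of appearance:
#' records are scanned in input order, each record left to right (forward
#' track first, then the reverse-complement track in duplex mode), and IDs
#' 1, 2, ... are given at first sighting. k-mers containing non-A/C/G/T
#' characters are skipped. An optional seeded shuffle reassigns the IDs at
#' random (the ID values carry no meaning; classification is robust to the
#' assignment), and `build_fraction` builds the table from a seeded
#' subsample of the records for robustness experiments.
#'
#' @param records Record data.frame (or a `benchmark_dataset`).
#' @param k Word length.
#' @param track_mode `"duplex"` (forward plus reverse-complement track,
#'   default) or `"forward"`.
#' @param build_fraction Fraction of records (0, 1] used to build the table.
#' @param shuffle If `TRUE`, permute the ID assignment with `seed`.
#' @param seed Seed used for subsampling/shuffling (required when either is
#'   active).
#' @return A `kmer_dictionary`: list with `k`, `entries` (named integer
#'   vector, kmer -> ID), `size` (P), `track_mode`, `build_fraction`, `seed`.
#' @export
build_dictionary <- function(records, k, track_mode = c("duplex", "forward"),
                             build_fraction = 1, shuffle = FALSE,
                             seed = NULL) {
  track_mode <- match.arg(track_mode)
  if (inherits(records, "benchmark_dataset")) records <- records$records
  sequences <- records$sequence
  if (length(sequences) == 0L) stop("no records supplied", call. = FALSE)
  if (build_fraction <= 0 || build_fraction > 1) {
    stop("build_fraction must be in (0, 1]", call. = FALSE)
  }
  if ((build_fraction < 1 || shuffle) && is.null(seed)) {
    stop("seed is required for subsampling or shuffling", call. = FALSE)
  }
  if (build_fraction < 1) {
    n_keep <- max(1L, floor(build_fraction * length(sequences)))
    # seeded subsample, original record order preserved
    old <- .Random.seed_save()
    set.seed(seed)
    idx <- sort(sample.int(length(sequences), n_keep))
    .Random.seed_restore(old)
    sequences <- sequences[idx]
  }
  stream <- record_kmer_stream(sequences, k, track_mode)
  stream <- stream[is_valid_kmer(stream)]
  if (length(stream) == 0L) stop("no valid k-mer found in records",
                                 call. = FALSE)
  kmers <- unique(stream)
  ids <- seq_along(kmers)
  if (shuffle) {
    old <- .Random.seed_save()
    set.seed(seed)
    ids <- sample(ids)
    .Random.seed_restore(old)
  }
  structure(list(k = as.integer(k),
                 entries = setNames(as.integer(ids), kmers),
                 size = length(kmers),
                 track_mode = track_mode,
                 build_fraction = build_fraction,
                 seed = seed),
            class = "kmer_dictionary")
}

# save/restore the global RNG state so seeded sub-steps do not perturb the
# caller's random stream
.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
}
.Random.seed_restore <- function(state) {
  if (!is.null(state)) assign(".Random.seed", state, envir = globalenv())
  invisible(NULL)
}

#' @export
print.kmer_dictionary <- function(x, ...) {
  cat("kmer_dictionary: ", x$size, " ", x$k, "-mers (", x$track_mode,
      " tracks)\n", sep = "")
  invisible(x)
}

#' Serialize a dictionary to TSV
#'
#' One `kmer<TAB>id` row per entry, sorted by ID, preceded by a single
#' `#`-prefixed JSON header line recording k, P, track mode, build fraction
#' and seed. The output is byte-stable for a given dictionary.
#'
#' @param dict A `kmer_dictionary`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_dictionary <- function(dict, path) {
  header <- jsonlite::toJSON(
    list(k = dict$k, P = dict$size, track_mode = dict$track_mode,
         build_fraction = dict$build_fraction,
         seed = if (is.null(dict$seed)) NA else dict$seed),
    auto_unbox = TRUE, na = "null")
  ord <- order(dict$entries)
  lines <- c(paste0("#", header),
             paste(names(dict$entries)[ord], dict$entries[ord], sep = "\t"))
  writeLines(lines, path)
  invisible(path)
}

#' Read a serialized dictionary
#'
#' @param path Path written by [write_dictionary()].
#' @return A `kmer_dictionary`.
#' @export
read_dictionary <- function(path) {
  lines <- readLines(path)
  header <- jsonlite::fromJSON(sub("^#", "", lines[1]))
  body <- strsplit(lines[-1], "\t", fixed = TRUE)
  kmers <- vapply(body, `[`, character(1), 1L)
  ids <- as.integer(vapply(body, `[`, character(1), 2L))
  structure(list(k = as.integer(header$k),
                 entries = setNames(ids, kmers),
                 size = as.integer(header$P),
                 track_mode = header$track_mode,
                 build_fraction = header$build_fraction,
                 seed = if (is.null(header$seed) || is.na(header$seed)) NULL
                        else header$seed),
            class = "kmer_dictionary")
}

#' Encode a sequence as a position-ID vector
#'
#' Replaces each sliding-window k-mer with its dictionary ID, or 0 when the
#' k-mer is absent from the dictionary (including any window containing a
#' non-A/C/G/T character). In duplex mode the forward-track IDs are followed
#' by the reverse-complement-track IDs (the k-mers of the reverse complement
#' read 5'->3').
#'
#' @param sequence A single sequence string.
#' @param dict A `kmer_dictionary`.
#' @param track_mode `"duplex"` or `"forward"`; defaults to the mode the
#'   dictionary was built with.
#' @return Integer vector of length `n - k + 1` (forward) or
#'   `2 * (n - k + 1)` (duplex).
#' @export
encode <- function(sequence, dict, track_mode = dict$track_mode) {
  track_mode <- match.arg(track_mode, c("duplex", "forward"))
  lookup <- function(kmers) {
    ids <- unname(dict$entries[kmers])
    ids[is.na(ids)] <- 0L
    as.integer(ids)
  }
  fw <- lookup(extract_kmers(sequence, dict$k))
  if (track_mode == "forward") return(fw)
  c(fw, lookup(extract_kmers(reverse_complement(sequence), dict$k)))
}

#' Encode a record collection into a position-ID matrix
#'
#' @param records Record data.frame, or the `records` element of a
#'   [binary_view()] result.
#' @param dict A `kmer_dictionary`.
#' @param track_mode `"duplex"` or `"forward"`.
#' @param labels Optional 0/1 (or 0/1/2) label vector copied onto the
#'   matrix.
#' @param strict When `TRUE` (default) all records must share one length.
#' @param n Declared sequence length in bp; required only for an empty
#'   record collection (so the column count is still defined), otherwise
#'   taken from the records.
#' @return An `encoded_matrix`: list with `ids` (samples x positions integer
#'   matrix), `labels`, `k`, `track_mode`, `n` (source bp).
#' @export
encode_dataset <- function(records, dict, track_mode = dict$track_mode,
                           labels = NULL, strict = TRUE, n = NULL) {
  track_mode <- match.arg(track_mode, c("duplex", "forward"))
  sequences <- records$sequence
  if (!is.null(labels) && length(labels) != length(sequences)) {
    stop("labels length (", length(labels), ") != record count (",
         length(sequences), ")", call. = FALSE)
  }
  n <- if (length(sequences)) nchar(sequences[1])
       else if (!is.null(n)) as.integer(n) else 0L
  if (strict && length(sequences) && any(nchar(sequences) != n)) {
    stop("mixed sequence lengths in strict mode", call. = FALSE)
  }
  tracks <- if (track_mode == "duplex") 2L else 1L
  ncols <- tracks * max(0L, n - dict$k + 1L)
  ids <- matrix(0L, nrow = length(sequences), ncol = ncols)
  for (i in seq_along(sequences)) {
    ids[i, ] <- encode(sequences[i], dict, track_mode)
  }
  structure(list(ids = ids, labels = labels, k = dict$k,
                 track_mode = track_mode, n = as.integer(n)),
            class = "encoded_matrix")
}

#' @export
print.encoded_matrix <- function(x, ...) {
  cat("encoded_matrix: ", nrow(x$ids), " samples x ", ncol(x$ids),
      " positions (k = ", x$k, ", ", x$track_mode, ")\n", sep = "")
  invisible(x)
}

#' Export an encoded matrix as CSV
#'
#' Integer cells, one row per sample, optional final `label` column.
#'
#' @param em An `encoded_matrix`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_encoded_matrix <- function(em, path) {
  out <- as.data.frame(em$ids)
  names(out) <- paste0("p", seq_len(ncol(em$ids)))
  if (!is.null(em$labels)) out$label <- em$labels
  write.table(out, path, sep = ",", row.names = FALSE, quote = FALSE)
  invisible(path)
}
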