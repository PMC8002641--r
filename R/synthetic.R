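#' Planted-motif specification
#'
#' Describes one position-specific signal planted by the synthetic
#' generator: a short motif written over the background at fixed offsets,
#' with a per-class planting probability expressing the class gradient
#' strong >= weak >= background.
#'
#' @param motif Motif string over A/C/G/T.
#' @param positions 1-based start offsets at which the motif may be
#'   planted.
#' @param p_strong,p_weak,p_background Planting probabilities per record
#'   for the three classes (each in \[0, 1\]).
#' @return A `motif_spec` list.
#' @export
motif_spec <- function(motif, positions, p_strong = 1, p_weak = 1,
                       p_background = 0) {
  stopifnot(nchar(motif) >= 1, all(positions >= 1),
            p_strong >= 0, p_strong <= 1, p_weak >= 0, p_weak <= 1,
            p_background >= 0, p_background <= 1)
  structure(list(motif = toupper(motif), positions = as.integer(positions),
                 p_strong = p_strong, p_weak = p_weak,
                 p_background = p_background),
            class = "motif_spec")
}

default_motifs <- function(length = 200L) {
  # two position-specific motifs in the first half of the sequence; the
  # strong/weak classes differ only in planting probability, making the
  # strength task learnable but harder than detection
  list(motif_spec("ACGTACGT", pmin(c(21L, 121L), length - 8L),
                  p_strong = 0.9, p_weak = 0.6, p_background = 0.05),
       motif_spec("TTGACA", pmin(61L, length - 6L),
                  p_strong = 0.9, p_weak = 0.6, p_background = 0.05))
}

#' Synthetic benchmark configuration
#'
#' Defaults mirror the real benchmark's shape: 742 strong + 742 weak
#' enhancers and 1484 non-enhancers of 200 bp, uniform base composition,
#' with two planted position-specific motifs distinguishing the classes.
#'
#' @param n_strong,n_weak,n_non Class sizes.
#' @param length Sequence length in bp.
#' @param motifs List of [motif_spec()]s.
#' @param base_composition Named probabilities over A, C, G, T (sum 1).
#' @param seed Integer seed; generation is fully reproducible from it.
#' @return A `synthetic_config` list.
#' @export
synthetic_config <- function(n_strong = 742L, n_weak = 742L, n_non = 1484L,
                             length = 200L, motifs = default_motifs(length),
                             base_composition = c(A = 0.25, C = 0.25,
                                                  G = 0.25, T = 0.25),
                             seed = 1L) {
  stopifnot(n_strong >= 0, n_weak >= 0, n_non >= 0, length >= 1,
            abs(sum(base_composition) - 1) < 1e-8)
  for (m in motifs) {
    if (any(m$positions + nchar(m$motif) - 1L > length)) {
      stop("motif '", m$motif, "' overflows the ", length, "-bp sequence",
           call. = FALSE)
    }
  }
  structure(list(n_strong = as.integer(n_strong),
                 n_weak = as.integer(n_weak), n_non = as.integer(n_non),
                 length = as.integer(length), motifs = motifs,
                 base_composition = base_composition,
                 seed = as.integer(seed)),
            class = "synthetic_config")
}

#' Generate a synthetic benchmark dataset
#'
#' Draws i.i.d. background bases from the configured composition, then for
#' each record and motif writes the motif over the background at each
#' listed offset with the record's class planting probability. Byte-
#' reproducible from the seed.
#'
#' @param config A [synthetic_config()].
#' @return A labelled `benchmark_dataset`.
#' @export
generate_dataset <- function(config) {
  old <- .Random.seed_save()
  set.seed(config$seed)
  bases <- c("A", "C", "G", "T")
  gen_class <- function(n, label, prob_field) {
    if (n == 0L) {
      return(data.frame(id = character(), sequence = character(),
                        label = character(), stringsAsFactors = FALSE))
    }
    chars <- matrix(sample(bases, n * config$length, replace = TRUE,
                           prob = config$base_composition),
                    nrow = n, ncol = config$length)
    for (m in config$motifs) {
      p <- m[[prob_field]]
      if (p == 0) next
      mot <- strsplit(m$motif, "", fixed = TRUE)[[1]]
      for (pos in m$positions) {
        plant <- runif(n) < p
        if (any(plant)) {
          chars[plant, pos:(pos + length(mot) - 1L)] <-
            matrix(mot, nrow = sum(plant), ncol = length(mot), byrow = TRUE)
        }
      }
    }
    data.frame(id = paste0(sub("_enhancer$", "", label), "_", seq_len(n)),
               sequence = apply(chars, 1L, paste, collapse = ""),
               label = label, stringsAsFactors = FALSE)
  }
  strong <- gen_class(config$n_strong, "strong_enhancer", "p_strong")
  weak <- gen_class(config$n_weak, "weak_enhancer", "p_weak")
  non <- gen_class(config$n_non, "non_enhancer", "p_background")
  .Random.seed_restore(old)
  assemble_dataset(strong, weak, non, expected_length = config$length)
}

#' Encoded columns carrying planted signal
#'
#' Ground truth for selection experiments: the encoded-matrix columns whose
#' k-mer window overlaps at least one planted motif offset, on each active
#' track. A forward-track column j covers bases j..j+k-1; a duplex
#' reverse-track column j' covers the same physical bases as forward window
#' n-k+2-j' (the reverse complement's 5'->3' windows read the sequence from
#' its 3' end).
#'
#' @param config A [synthetic_config()].
#' @param k Word length.
#' @param track_mode `"duplex"` or `"forward"`.
#' @return Sorted integer vector of 1-based column indices.
#' @export
planted_truth <- function(config, k, track_mode = c("duplex", "forward")) {
  track_mode <- match.arg(track_mode)
  n <- config$length
  w <- n - k + 1L
  spans <- do.call(rbind, lapply(config$motifs, function(m) {
    cbind(start = m$positions, end = m$positions + nchar(m$motif) - 1L)
  }))
  if (is.null(spans) || nrow(spans) == 0L) return(integer(0))
  overlaps <- function(a1, a2) {
    any(spans[, "start"] <= a2 & spans[, "end"] >= a1)
  }
  fw <- which(vapply(seq_len(w), function(j) overlaps(j, j + k - 1L),
                     logical(1)))
  if (track_mode == "forward") return(fw)
  rc <- which(vapply(seq_len(w), function(j) {
    lo <- n - (j + k - 1L) + 1L          # physical span of RC window j
    overlaps(lo, lo + k - 1L)
  }, logical(1)))
  sort(c(fw, w + rc))
}

#' Selection-recovery curve across effect sizes
#'
#' For each planting probability in the grid, repeatedly generates a
#' dataset, scores all positions with the chi-squared screen on the
#' detection labels, and records the fraction of planted columns ranked in
#' the informative (small-p) half. Near-chance recovery (~0.5) is expected
#' when the planting probability equals the background rate; recovery
#' should rise towards 1 with the class contrast.
#'
#' @param base_config A [synthetic_config()]; its motifs' `p_strong`/
#'   `p_weak` are overridden by the grid values.
#' @param p_grid Planting probabilities for the enhancer classes.
#' @param n_seeds Replicates per grid point (default 20).
#' @param k Word length (default 2).
#' @param track_mode `"duplex"` or `"forward"`.
#' @return Data.frame with columns `p_plant`, `recovery` (mean over seeds),
#'   and `sd`.
#' @export
effect_size_curve <- function(base_config, p_grid, n_seeds = 20L, k = 2L,
                              track_mode = c("duplex", "forward")) {
  track_mode <- match.arg(track_mode)
  rows <- lapply(p_grid, function(p) {
    recov <- vapply(seq_len(n_seeds), function(s) {
      cfg <- base_config
      cfg$motifs <- lapply(cfg$motifs, function(m) {
        m$p_strong <- p; m$p_weak <- p; m
      })
      cfg$seed <- base_config$seed + s
      ds <- generate_dataset(cfg)
      planted_column_recovery(ds, cfg, k, track_mode)
    }, numeric(1))
    data.frame(p_plant = p, recovery = mean(recov), sd = sd(recov))
  })
  do.call(rbind, rows)
}

#' Fraction of planted columns scored as informative
#'
#' Builds the dictionary and encoding for a generated dataset, scores all
#' positions on the detection labels, and returns the fraction of
#' [planted_truth()] columns whose summed p-value falls in the smaller
#' (informative) half of all column scores.
#'
#' @param dataset A generated `benchmark_dataset`.
#' @param config The [synthetic_config()] that produced it.
#' @param k Word length.
#' @param track_mode `"duplex"` or `"forward"`.
#' @return Recovery fraction in \[0, 1\].
#' @export
planted_column_recovery <- function(dataset, config, k = 2L,
                                    track_mode = c("duplex", "forward")) {
  track_mode <- match.arg(track_mode)
  truth <- planted_truth(config, k, track_mode)
  if (length(truth) == 0L) return(NA_real_)
  dict <- build_dictionary(dataset$records, k, track_mode)
  det <- binary_view(dataset, "detection")
  em <- encode_dataset(det$records, dict, track_mode, labels = det$labels)
  score <- score_all_positions(em)
  informative <- rank(score$position_pvalues, ties.method = "first") <=
    floor(length(score$position_pvalues) / 2)
  mean(informative[truth])
}

#' Write synthetic ground truth as JSON
#'
#' Emits the motif specifications, planted columns and seed of a synthetic
#' run for downstream verification.
#'
#' @param config A [synthetic_config()].
#' @param k Word length used downstream.
#' @param track_mode Track mode used downstream.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_ground_truth <- function(config, k, track_mode, path) {
  obj <- list(seed = config$seed, length = config$length,
              n_strong = config$n_strong, n_weak = config$n_weak,
              n_non = config$n_non,
              motifs = lapply(config$motifs, unclass),
              k = k, track_mode = track_mode,
              planted_columns = planted_truth(config, k, track_mode))
  writeLines(jsonlite::toJSON(obj, auto_unbox = TRUE, digits = NA), path)
  invisible(path)
}
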