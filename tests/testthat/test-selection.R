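test_that("one-hot expansion builds the working matrices", {
  w <- onehot_expand(c(1L, 1L, 2L, 2L), c(1L, 1L, 0L, 0L))
  expect_equal(dim(w$X), c(4L, 2L))
  expect_equal(unname(w$vFeatureSum), c(2, 2))
  expect_equal(unname(w$vProbClass), c(0.5, 0.5))
  expect_equal(w$N1, 2L)

  w1 <- onehot_expand(c(7L, 7L, 7L), c(1L, 0L, 1L))
  expect_equal(ncol(w1$X), 1L)
  expect_equal(unname(w1$vFeatureSum), 3)

  set.seed(20)
  col <- sample(1:12, 50, replace = TRUE)
  w2 <- onehot_expand(col, rep(0:1, 25))
  expect_equal(ncol(w2$X), length(unique(col)))

  expect_error(onehot_expand(c(1L, 2L), c(1L, 1L)), "both classes")
  expect_error(onehot_expand(integer(0), integer(0)), "positive length")
})

test_that("per-position chi-squared statistics match the worked example", {
  w <- onehot_expand(c(1L, 1L, 2L, 2L), c(1L, 1L, 0L, 0L))
  res <- chi2_position(w)
  expect_equal(unname(res$vObserved), rbind(c(0, 2), c(2, 0)))
  expect_equal(unname(res$vExpected), rbind(c(1, 1), c(1, 1)))
  expect_equal(unname(res$category_stats), c(2, 2))
  # summed upper-tail p-values at df = 1
  expect_equal(res$position_pvalue,
               2 * pchisq(2, df = 1, lower.tail = FALSE), tolerance = 1e-12)
  expect_equal(res$position_pvalue, 0.31460, tolerance = 1e-4)

  # perfectly uninformative column
  res0 <- chi2_position(onehot_expand(rep(1L, 4), c(1L, 1L, 0L, 0L)))
  expect_equal(unname(res0$category_stats), 0)
  expect_equal(res0$position_pvalue, 1)
})

test_that("chi-squared statistics agree with the contingency-table oracle", {
  set.seed(31)
  for (rep in 1:50) {
    n <- sample(8:30, 1)
    labels <- c(0L, 1L, sample(0:1, n - 2, replace = TRUE))
    column <- sample(1:6, n, replace = TRUE)
    mine <- chi2_position(onehot_expand(column, labels))
    oracle <- chi2_margin_oracle(column, labels)
    expect_equal(unname(mine$category_stats), oracle$stats,
                 tolerance = 1e-12)
    expect_equal(mine$position_pvalue, oracle$position_pvalue,
                 tolerance = 1e-12)
  }
})

test_that("position scores are invariant to row order and ID relabeling", {
  set.seed(40)
  column <- sample(1:5, 40, replace = TRUE)
  labels <- rep(0:1, 20)
  p0 <- chi2_position(onehot_expand(column, labels))$position_pvalue
  perm <- sample(40)
  p_rows <- chi2_position(onehot_expand(column[perm],
                                        labels[perm]))$position_pvalue
  relabel <- c(9L, 2L, 14L, 5L, 11L)     # arbitrary injective ID map
  p_ids <- chi2_position(onehot_expand(relabel[column],
                                       labels))$position_pvalue
  expect_equal(p_rows, p0, tolerance = 1e-12)
  expect_equal(p_ids, p0, tolerance = 1e-12)
})

test_that("score_all_positions scores every column (and only uses labels)", {
  em <- separable_em(n = 40, t_cols = 12, seed = 2)
  tab <- score_all_positions(em)
  expect_length(tab$position_pvalues, 12L)
  # the scan route must equal the one-hot matrix route column by column
  for (j in c(1L, 4L, 12L)) {
    expect_equal(tab$position_pvalues[j],
                 chi2_position(onehot_expand(em$ids[, j],
                                             em$labels))$position_pvalue,
                 tolerance = 1e-12)
  }
  # planted columns score as informative (small p)
  expect_true(all(rank(tab$position_pvalues)[3:6] <= 6))

  const <- em
  const$ids[] <- 3L
  expect_equal(score_all_positions(const)$position_pvalues, rep(1, 12))
  unlab <- em; unlab$labels <- NULL
  expect_error(score_all_positions(unlab), "no labels")
  onecl <- em; onecl$labels <- rep(1L, nrow(em$ids))
  expect_error(score_all_positions(onecl), "both classes")
})

test_that("top-K removal is nested, tie-stable and bounded", {
  em <- separable_em(n = 40, t_cols = 12, seed = 3)
  tab <- score_all_positions(em)
  expect_equal(remove_top_k(tab, 0)$removed, rep(FALSE, 12))
  m3 <- remove_top_k(tab, 3); m7 <- remove_top_k(tab, 7)
  expect_equal(sum(m3$removed), 3L)
  expect_true(all(which(m3$removed) %in% which(m7$removed)))
  # equal p-values everywhere: lowest column indices removed first
  const <- em; const$ids[] <- 3L
  mt <- remove_top_k(score_all_positions(const), 3)
  expect_equal(which(mt$removed), 1:3)
  expect_error(remove_top_k(tab, 12), "K must satisfy")
  expect_error(remove_top_k(tab, -1), "K must satisfy")
})

test_that("masks apply uniformly to train and test matrices", {
  em_tr <- separable_em(n = 40, t_cols = 12, seed = 4)
  em_te <- separable_em(n = 20, t_cols = 12, seed = 5)
  tab <- remove_top_k(score_all_positions(em_tr), 4)
  a_tr <- apply_mask(em_tr, tab)
  a_te <- apply_mask(em_te, tab$removed)
  expect_equal(ncol(a_tr$ids), 8L)
  expect_identical(a_tr$kept_columns, a_te$kept_columns)
  # survivor order preserved
  expect_equal(a_tr$ids, em_tr$ids[, !tab$removed])
  expect_identical(apply_mask(em_tr, rep(FALSE, 12))$ids, em_tr$ids)
  expect_error(apply_mask(em_tr, rep(FALSE, 5)), "mask length")
})

test_that("removal sweep enumerates coarse then fine steps", {
  em <- separable_em(n = 40, t_cols = 60, vocab = 8, seed = 6)
  tab <- score_all_positions(em)
  stub <- function(mask) {
    list(Sn = 1, Sp = 1, Acc = 1 - sum(mask) / 1000, MCC = 0.5, AUC = 0.9)
  }
  sw <- removal_sweep(tab, stub, coarse_step = 5, coarse_max = 45,
                      fine_steps = 5)
  expect_equal(sw$K, c(seq(0, 45, by = 5), 46:50))
  expect_equal(sum(sw$stage == "coarse"), 10L)
  expect_equal(sum(sw$stage == "fine"), 5L)
  expect_equal(names(sw), c("K", "stage", "Sn", "Sp", "Acc", "MCC", "AUC"))
})

test_that("score-table and mask serializations round-trip", {
  em <- separable_em(n = 30, t_cols = 10, seed = 7)
  tab <- remove_top_k(score_all_positions(em), 3)
  fs <- withr::local_tempfile(); fm <- withr::local_tempfile()
  write_score_table(tab, fs)
  st <- read.table(fs, header = TRUE, sep = "\t")
  expect_equal(nrow(st), 10L)
  expect_equal(sum(st$removed), 3L)
  write_mask(tab, fm)
  mask <- read_mask(fm)
  expect_equal(as.logical(mask), tab$removed)
  expect_equal(attr(mask, "K"), 3L)
})
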