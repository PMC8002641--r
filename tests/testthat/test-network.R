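test_that("network description matches the layer contract", {
  cfg <- model_config()
  net <- build_network(cfg, input_columns = 353, vocab_size = 16)
  expect_equal(2L * cfg$lstm_size, 128L)       # per-timestep biLSTM width
  expect_equal(net$vocab, 17L)                 # IDs 0..P
  expect_equal(net$layers[1], "embedding")
  expect_equal(net$layers[length(net$layers)], "dense_sigmoid")
  expect_error(build_network(cfg, 0, 16), "input_columns")
  expect_error(build_network(cfg, 10, 16, n_outputs = 2), "n_outputs")
})

test_that("analytic gradients match finite differences", {
  set.seed(42)
  cfg <- model_config(Q = 5, lstm_size = 4, dropout = 0, batch_size = 3,
                      attention_size = 3, seed = 1)
  for (n_out in c(1L, 3L)) {
    net <- build_network(cfg, input_columns = 6, vocab_size = 7,
                         n_outputs = n_out)
    params <- seqpose:::init_params(net)
    state <- list(bn_mean = rep(0, 8), bn_var = rep(1, 8))
    ids <- matrix(sample(0:7, 4 * 6, replace = TRUE), 4, 6)
    y <- if (n_out == 1L) c(1, 0, 1, 0) else c(0, 2, 1, 1)
    loss_fn <- function(p) {
      fw <- seqpose:::network_forward(p, state, ids, net, training = TRUE)
      seqpose:::network_loss(fw$prob, y, n_out)
    }
    fw <- seqpose:::network_forward(params, state, ids, net,
                                    training = TRUE, keep_cache = TRUE)
    gr <- seqpose:::network_backward(params, net, fw, y)
    eps <- 1e-5
    for (nm in names(params)) {
      picks <- sample(length(params[[nm]]), min(length(params[[nm]]), 6))
      for (ii in picks) {
        pp <- params; pp[[nm]][ii] <- pp[[nm]][ii] + eps
        pm <- params; pm[[nm]][ii] <- pm[[nm]][ii] - eps
        num <- (loss_fn(pp) - loss_fn(pm)) / (2 * eps)
        expect_equal(gr[[nm]][ii], num, tolerance = 1e-4,
                     label = paste0("d", nm, "[", ii, "]"))
      }
    }
  }
})

test_that("training is deterministic under a fixed seed", {
  em <- separable_em(n = 32, t_cols = 10, seed = 1)
  va <- separable_em(n = 16, t_cols = 10, seed = 2)
  cfg <- tiny_config()
  net <- build_network(cfg, 10, 6)
  h1 <- train_head(net, em, va, cfg)
  h2 <- train_head(net, em, va, cfg)
  expect_identical(h1$training_log, h2$training_log)
  expect_identical(predict(h1, va)$prob, predict(h2, va)$prob)
})

test_that("attention weights are a distribution over timesteps", {
  em <- separable_em(n = 32, t_cols = 10, seed = 3)
  va <- separable_em(n = 16, t_cols = 10, seed = 4)
  cfg <- tiny_config()
  head <- train_head(build_network(cfg, 10, 6), em, va, cfg)
  pr <- predict(head, va, return_attention = TRUE)
  expect_true(all(pr$attention >= 0))
  expect_equal(rowSums(pr$attention), rep(1, 16), tolerance = 1e-12)
})

test_that("inference is invariant to batch partitioning", {
  em <- separable_em(n = 40, t_cols = 10, seed = 5)
  va <- separable_em(n = 16, t_cols = 10, seed = 6)
  cfg <- tiny_config()
  head <- train_head(build_network(cfg, 10, 6), em, va, cfg)
  all_at_once <- predict(head, em)$prob
  net <- build_network(cfg, 10, 6)
  chunked <- seqpose:::head_probs(head$params, head$state, em$ids, net,
                                  chunk = 7L)
  expect_equal(all_at_once, drop(chunked), tolerance = 1e-12)
})

test_that("the decision rule is >= threshold, and edges are handled", {
  em <- separable_em(n = 32, t_cols = 10, seed = 7)
  va <- separable_em(n = 16, t_cols = 10, seed = 8)
  cfg <- tiny_config()
  head <- train_head(build_network(cfg, 10, 6), em, va, cfg)
  # zero the output layer: every probability is exactly 0.5 -> call 1
  head$params$Wd[] <- 0
  head$params$bd[] <- 0
  pr <- predict(head, va)
  expect_true(all(pr$prob == 0.5))
  expect_true(all(pr$call == 1L))
  # empty input -> empty output
  empty <- va; empty$ids <- va$ids[0, , drop = FALSE]
  pr0 <- predict(head, empty)
  expect_length(pr0$prob, 0L)
  expect_length(pr0$call, 0L)
  # column mismatch names both counts
  expect_error(predict(head, separable_em(n = 4, t_cols = 8, seed = 9)),
               "8.*10|10.*8")
})

test_that("degenerate training inputs error out", {
  cfg <- tiny_config()
  net <- build_network(cfg, 10, 6)
  em <- separable_em(n = 32, t_cols = 10, seed = 10)
  va <- separable_em(n = 8, t_cols = 10, seed = 11)
  empty <- em; empty$ids <- em$ids[0, , drop = FALSE]; empty$labels <- integer(0)
  expect_error(train_head(net, empty, va, cfg), "empty")
  onecl <- em; onecl$labels <- rep(1L, 32)
  expect_error(train_head(net, onecl, va, cfg), "classes")
})

test_that("a separable task is learned and a shuffled one is not", {
  em <- separable_em(n = 96, t_cols = 14, seed = 12)
  va <- separable_em(n = 32, t_cols = 14, seed = 13)
  cfg <- tiny_config(max_epochs = 4L)
  net <- build_network(cfg, 14, 6)
  head <- train_head(net, em, va, cfg)
  expect_gte(max(head$training_log$val_acc), 0.9)
  # reloaded head reproduces predictions bit for bit
  f <- withr::local_tempfile(fileext = ".rds")
  saveRDS(head, f)
  expect_identical(predict(readRDS(f), va)$prob, predict(head, va)$prob)
})

test_that("the three-class head trains, sums to one, and needs 3 classes", {
  em <- separable_em3(n = 96, t_cols = 14, seed = 14)
  va <- separable_em3(n = 33, t_cols = 14, seed = 15)
  cfg <- tiny_config(max_epochs = 4L)
  net <- build_network(cfg, 14, 6, n_outputs = 3)
  head <- train_three_class(net, em, va, cfg)
  pr <- predict(head, va)
  expect_equal(rowSums(pr$prob), rep(1, 33), tolerance = 1e-12)
  acc <- mean(pr$call == c("non_enhancer", "weak_enhancer",
                           "strong_enhancer")[va$labels + 1L])
  expect_gte(acc, 0.85)
  two <- em; two$labels[two$labels == 2L] <- 1L
  expect_error(train_three_class(net, two, va, cfg), "classes")
  expect_equal(three_class_labels(c("non_enhancer", "weak_enhancer",
                                    "strong_enhancer")), 0:2)
})

test_that("masking signal positions before training degrades accuracy", {
  accs <- matrix(0, nrow = 10, ncol = 2)
  for (s in 1:10) {
    em <- separable_em(n = 64, t_cols = 12, seed = 100 + s,
                       signal_cols = 3:6)
    va <- separable_em(n = 32, t_cols = 12, seed = 200 + s,
                       signal_cols = 3:6)
    cfg <- tiny_config(max_epochs = 3L)
    h_full <- train_head(build_network(cfg, 12, 6), em, va, cfg)
    drop_cols <- function(e) {
      e$ids <- e$ids[, -(3:6), drop = FALSE]; e
    }
    h_masked <- train_head(build_network(cfg, 8, 6), drop_cols(em),
                           drop_cols(va), cfg)
    accs[s, ] <- c(max(h_full$training_log$val_acc),
                   max(h_masked$training_log$val_acc))
  }
  expect_gt(mean(accs[, 1]), mean(accs[, 2]))
  expect_gte(mean(accs[, 1]) - mean(accs[, 2]), 0.15)
})
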