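test_that("initialization is seeded, orthogonal and Xavier-bounded", {
  cfg <- small_model_config(n_classes = 3L)
  p1 <- init_params(cfg, "beatfusion", seed = 5)
  p2 <- init_params(cfg, "beatfusion", seed = 5)
  expect_identical(p1, p2)
  expect_false(identical(p1, init_params(cfg, "beatfusion", seed = 6)))

  # recurrent blocks orthogonal per gate
  for (dir in c("fwd", "bwd")) {
    for (u in c("Uz", "Ur", "Uh")) {
      q <- p1$gru[[dir]][[u]]
      expect_equal(crossprod(q), diag(nrow(q)), tolerance = 1e-6)
    }
    for (w in c("Wz", "Wr", "Wh")) {
      q <- p1$gru[[dir]][[w]]  # wide matrix: orthonormal rows
      expect_equal(tcrossprod(q), diag(nrow(q)), tolerance = 1e-6)
    }
  }
  # Xavier bounds for convolutions
  k <- cfg$kernel_size
  c_in <- cfg$D
  for (l in seq_along(cfg$conv_channels)) {
    c_out <- cfg$conv_channels[l]
    lim <- sqrt(6 / (c_in * k + c_out * k))
    expect_true(all(abs(p1$conv[[l]]$W) <= lim))
    expect_true(all(p1$conv[[l]]$b == 0))
    c_in <- c_out
  }
})

test_that("a zero learning rate leaves parameters untouched", {
  cfg <- tiny_cfg(n_classes = 2L)
  mod <- build_model("beatfusion", cfg, seed = 1)
  inp <- random_beat_input(cfg, 6, seed = 2)
  set.seed(3)
  data <- list(x = inp, y = matrix(rbinom(12, 1, 0.5), 6, 2))
  trained <- fit(mod, data, train_config(batch_size = 3, learning_rate = 0,
                                         epochs = 2, seed = 4))
  expect_identical(trained$params, mod$params)
})

test_that("training reduces the loss and L2 shrinks the weights", {
  td <- synth_task_data("beatfusion")
  sub <- beatfuse:::slice_data(td$train, 1:80)
  cfg <- small_model_config(n_classes = 3L)
  runs <- lapply(c(0, 1e-2), function(lambda) {
    cfg$l2_weight <- lambda
    m <- build_model("beatfusion", cfg, seed = 9)
    fit(m, sub, train_config(batch_size = 32, learning_rate = 1e-3,
                             epochs = 3, seed = 9))
  })
  for (m in runs) {
    expect_lt(tail(m$history$train_loss, 1), m$history$train_loss[1])
  }
  expect_lt(l2_penalty(runs[[2]]$params), l2_penalty(runs[[1]]$params))
})

test_that("training is deterministic for a fixed seed", {
  td <- synth_task_data("beatfusion")
  sub <- beatfuse:::slice_data(td$train, 1:40)
  cfg <- small_model_config(n_classes = 3L)
  tc <- train_config(batch_size = 20, learning_rate = 1e-3, epochs = 2,
                     seed = 11)
  m1 <- fit(build_model("beatfusion", cfg, seed = 11), sub, tc)
  m2 <- fit(build_model("beatfusion", cfg, seed = 11), sub, tc)
  d <- abs(beatfuse:::flatten_params(m1$params) -
             beatfuse:::flatten_params(m2$params))
  expect_lt(max(d), 1e-12)
})

test_that("the cross-validation ensemble averages its fold models", {
  td <- synth_task_data("beatfusion")
  sub <- beatfuse:::slice_data(td$train, 1:36)
  cfg <- small_model_config(n_classes = 3L)
  tc <- train_config(batch_size = 12, learning_rate = 1e-3, epochs = 1,
                     folds = 2, seed = 13, early_stop_patience = 5)
  cv <- cross_validate_ensemble(sub, tc, cfg)
  expect_length(cv$models, 2)
  expect_true(all(cv$probs > 0 & cv$probs < 1))
  test_slice <- beatfuse:::slice_data(sub, cv$test_idx)
  manual <- (predict_probs(cv$models[[1]], test_slice) +
               predict_probs(cv$models[[2]], test_slice)) / 2
  expect_equal(cv$probs, manual, tolerance = 1e-12)
})

test_that("beat-window splits keep the 25:55 proportion", {
  expect_equal(beat_window_split(80), list(L_f = 25L, L_k = 55L))
  expect_equal(beat_window_split(160), list(L_f = 50L, L_k = 110L))
  expect_equal(beat_window_split(120), list(L_f = 38L, L_k = 82L))
})

test_that("the beat-length sweep re-derives windows and reports AUC per length", {
  task <- synth_task()
  tc <- train_config(batch_size = 16, learning_rate = 1e-3, epochs = 1,
                     seed = 17, early_stop_patience = 3)
  tab <- run_beat_length_sweep(task$train[1:30], task$test[1:12],
                               lengths = c(80, 120), tcfg = tc)
  expect_equal(tab$L_b, c(80, 120))
  expect_equal(tab$L_f, c(25L, 38L))
  expect_equal(tab$L_k, c(55L, 82L))
  expect_true(all(is.finite(tab$macro_auc)))
  expect_error(run_beat_length_sweep(task$train[1:4], task$test[1:4], 81,
                                     tcfg = tc), "divisible")
})

test_that("attention export aligns weights with detected beats", {
  cfg <- small_model_config(n_classes = 3L)
  m <- build_model("beatfusion", cfg, seed = 19)
  rec <- synthesize_record(synth_spec(snr_db = 20, seed = 23))
  ea <- export_attention(m, rec)
  expect_named(ea, c("beat_index", "peak_sample", "start_sample", "weight"))
  expect_equal(nrow(ea), length(detect_rpeaks(rec)$indices))
  expect_equal(sum(ea$weight), 1, tolerance = 1e-9)
  expect_equal(ea$start_sample, ea$peak_sample - 25L)
})
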