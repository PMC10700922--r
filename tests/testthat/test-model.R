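test_that("the GRU cell reproduces closed-form special cases", {
  g <- 3
  zero <- list(Wz = matrix(0, g, 2), Uz = matrix(0, g, g), bz = numeric(g),
               Wr = matrix(0, g, 2), Ur = matrix(0, g, g), br = numeric(g),
               Wh = matrix(0, g, 2), Uh = matrix(0, g, g), bh = numeric(g))
  v <- c(0.4, -1.2, 2.0)
  # all-zero parameters: gates are 0.5, candidate 0, so h_t = 0.5 h_{t-1}
  expect_equal(as.numeric(gru_cell_step(c(1, -1), v, zero)), 0.5 * v)
  expect_equal(as.numeric(gru_cell_step(c(0, 0), numeric(g), zero)),
               numeric(g))
  expect_error(gru_cell_step(c(NA, 1), v, zero), "finite")
})

test_that("the vectorized GRU matches the scalar oracle", {
  set.seed(5)
  for (i in 1:10) {
    p <- random_gru_params(4, 3)
    x <- rnorm(4)
    h <- rnorm(3)
    expect_equal(as.numeric(gru_cell_step(x, h, p)),
                 gru_cell_scalar(x, h, p), tolerance = 1e-12)
  }
})

test_that("forward and backward GRU passes mirror each other over time", {
  set.seed(6)
  p <- random_gru_params(3, 4)
  Xsteps <- lapply(1:7, function(t) matrix(rnorm(3 * 2), 3, 2))
  fwd_rev <- beatfuse:::gru_dir_fwd(rev(Xsteps), p)$H
  # with shared parameters, the backward pass at original step t is the
  # forward pass over the reversed sequence at step T + 1 - t
  fwd <- beatfuse:::gru_dir_fwd(Xsteps, p)$H
  manual <- matrix(0, 4, 2)
  for (t in 7:1) {
    manual <- gru_cell_step(Xsteps[[t]], manual, p)
    expect_equal(manual, fwd_rev[[7 + 1 - t]], tolerance = 1e-12)
  }
  expect_equal(fwd[[7]],
               beatfuse:::gru_dir_fwd(rev(rev(Xsteps)), p)$H[[7]])
})

test_that("a constant-input scalar GRU converges monotonically to a fixed point", {
  p <- list(Wz = matrix(0.5), Uz = matrix(0.1), bz = 0,
            Wr = matrix(0.3), Ur = matrix(0.2), br = 0,
            Wh = matrix(0.8), Uh = matrix(0.4), bh = 0)
  x <- matrix(1)
  h <- matrix(0)
  traj <- numeric(40)
  for (t in 1:40) {
    h <- gru_cell_step(x, h, p)
    traj[t] <- h
  }
  gaps <- abs(diff(traj))
  expect_true(all(diff(gaps) <= 1e-12))          # contraction
  expect_lt(gaps[39], 1e-8)                      # converged
})

test_that("the reference encoder produces the documented shapes", {
  model <- build_model("beatfusion", model_config(), seed = 1)
  rec <- synthesize_record(synth_spec(seed = 1, noise_sd = 0.02))
  bs <- segment_record(rec, rec$rpeaks_true, segmentation_config())
  fmap <- encode_beat_cnn(bs, model)
  expect_equal(dim(fmap), c(20, 256, 10))       # 80 / (2*2*2) = 10 steps
  feats <- encode_beat_rnn(fmap, model)
  expect_equal(dim(feats), c(20, 640))          # 64 features x 10 steps
  # first conv layer: 12 in-channels, 64 kernels of width 3, plus bias
  expect_equal(length(model$params$conv[[1]]$W) +
                 length(model$params$conv[[1]]$b), 2368)
})

test_that("the beat encoder shares weights across slots", {
  cfg <- tiny_cfg()
  model <- build_model("beatfusion", cfg, seed = 3)
  set.seed(8)
  beats <- array(rnorm(4 * 2 * 8), dim = c(4, 2, 8))
  beats[3, , ] <- beats[1, , ]                  # duplicate slot content
  fmap <- encode_beat_cnn(beats, model)
  expect_equal(fmap[3, , ], fmap[1, , ], tolerance = 1e-12)
  feats <- encode_beat_rnn(fmap, model)
  expect_equal(feats[3, ], feats[1, ], tolerance = 1e-12)
  # all-zero slots give identical encodings (bias/BN terms only)
  zb <- array(0, dim = c(3, 2, 8))
  zf <- encode_beat_cnn(zb, model)
  expect_equal(zf[1, , ], zf[2, , ], tolerance = 1e-12)
})

test_that("attention fusion weights behave as a masked softmax", {
  set.seed(9)
  p <- list(W = matrix(rnorm(3 * 5), 3, 5), b = rnorm(3), u = rnorm(3))
  f <- matrix(rnorm(5), 1, 5)[rep(1, 4), ]       # identical features
  out <- attention_fuse(f, c(1, 1, 1, 0), p)
  expect_equal(out$alpha, c(1 / 3, 1 / 3, 1 / 3, 0))
  expect_equal(out$f_att, as.numeric(f[1, ]))

  single <- attention_fuse(matrix(rnorm(5), 1, 5), 1, p)
  expect_equal(single$alpha, 1)

  # appending masked slots must not change weights or the fused vector
  fr <- matrix(rnorm(3 * 5), 3, 5)
  a <- attention_fuse(fr, c(1, 1, 1), p)
  b <- attention_fuse(rbind(fr, matrix(0, 2, 5)), c(1, 1, 1, 0, 0), p)
  expect_equal(b$alpha[1:3], a$alpha)
  expect_equal(b$alpha[4:5], c(0, 0))
  expect_equal(b$f_att, a$f_att)

  expect_error(attention_fuse(fr, c(0, 0, 0), p), "valid")
})

test_that("model variants emit probability matrices of the right shape", {
  cfg <- tiny_cfg(n_classes = 3L)
  inp <- random_beat_input(cfg, 4, seed = 10)
  set.seed(11)
  recs <- array(rnorm(4 * cfg$D * cfg$record_len),
                dim = c(4, cfg$D, cfg$record_len))
  for (variant in c("beatfusion", "backbone", "temporal_attention")) {
    m <- build_model(variant, cfg, seed = 4)
    x <- if (variant == "beatfusion") inp else recs
    fw <- model_forward(m, x, "eval")
    expect_equal(dim(fw$probs), c(4, 3))
    expect_true(all(fw$probs > 0 & fw$probs < 1))
    if (variant == "temporal_attention") {
      # one weight per encoder time step, not per beat
      expect_equal(ncol(fw$alpha), cfg$record_len / prod(cfg$conv_strides))
      expect_equal(rowSums(fw$alpha), rep(1, 4))
    }
  }
  expect_error(build_model("mystery", cfg), "'arg' should be one")
})

test_that("predictions ignore beat order and masked-slot contents", {
  cfg <- tiny_cfg(n_classes = 3L)
  m <- build_model("beatfusion", cfg, seed = 12)
  inp <- random_beat_input(cfg, 3, seed = 13)
  base <- model_forward(m, inp, "eval")

  # permute the valid slots of each record
  set.seed(14)
  perm <- inp
  for (i in 1:3) {
    s <- sum(inp$mask[i, ])
    pr <- sample(s)
    perm$beats[i, 1:s, , ] <- inp$beats[i, pr, , , drop = FALSE]
  }
  permuted <- model_forward(m, perm, "eval")
  expect_equal(permuted$probs, base$probs, tolerance = 1e-6)

  # scribble on masked slots
  noisy <- inp
  for (i in 1:3) {
    s <- sum(inp$mask[i, ])
    if (s < cfg$S_max) {
      noisy$beats[i, (s + 1):cfg$S_max, , ] <- 99
    }
  }
  scribbled <- model_forward(m, noisy, "eval")
  expect_equal(scribbled$probs, base$probs, tolerance = 1e-10)

  # duplicated records give identical rows in eval mode
  dup <- list(beats = inp$beats[c(1, 1, 2), , , , drop = FALSE],
              mask = inp$mask[c(1, 1, 2), , drop = FALSE])
  fw <- model_forward(m, dup, "eval")
  expect_identical(fw$probs[1, ], fw$probs[2, ])
})

test_that("losses match hand computations and validate inputs", {
  # z = 0.5 for every class: loss is C * ln 2
  expect_equal(bce_loss(matrix(0.5, 2, 4), matrix(c(0, 1), 2, 4)), 4 * log(2))
  # prediction equal to the label: loss is (numerically) zero
  y <- matrix(c(1, 0, 0, 1), 2, 2)
  expect_lt(bce_loss(y, y), 1e-5)
  # hand evaluation: -(ln 0.8 + ln 0.6)
  expect_equal(bce_loss(matrix(c(0.8, 0.4), 1, 2), matrix(c(1, 0), 1, 2)),
               -(log(0.8) + log(0.6)), tolerance = 1e-12)
  expect_error(bce_loss(matrix(0.5, 1, 2), matrix(c(2, 0), 1, 2)), "0/1")

  expect_equal(l2_penalty(c(3, 4)), 25)
  expect_equal(l2_penalty(numeric(0)), 0)
  expect_equal(l2_penalty(rep(1, 17)), 17)
  # on a parameter tree: weights only, no biases or batch-norm terms
  m <- build_model("beatfusion", tiny_cfg(), seed = 15)
  p <- m$params
  manual <- sum(p$conv[[1]]$W^2) + sum(p$conv[[2]]$W^2) +
    sum(unlist(lapply(p$gru, function(d) {
      sum(d$Wz^2) + sum(d$Uz^2) + sum(d$Wr^2) + sum(d$Ur^2) +
        sum(d$Wh^2) + sum(d$Uh^2)
    }))) +
    sum(p$step_lin$W^2) + sum(p$attn$W^2) + sum(p$attn$u^2) +
    sum(p$clf1$W^2) + sum(p$clf2$W^2)
  expect_equal(l2_penalty(p), manual, tolerance = 1e-12)
  # zeroing all parameters zeroes the penalty
  zeroed <- beatfuse:::tree_map(function(a) a * 0, p)
  expect_equal(l2_penalty(zeroed), 0)
})

test_that("analytic gradients of BCE + L2 match finite differences", {
  cfg <- tiny_cfg(n_classes = 2L)
  mod <- build_model("beatfusion", cfg, seed = 7)
  inp <- random_beat_input(cfg, 3, seed = 16)
  set.seed(17)
  y <- matrix(rbinom(6, 1, 0.5), 3, 2)
  loss_at <- function(vec) {
    mm <- mod
    mm$params <- beatfuse:::unflatten_params(mod$params, vec)
    set.seed(99)  # freeze dropout masks across evaluations
    fw <- model_forward(mm, inp, "train")
    bce_loss(fw$probs, y) + cfg$l2_weight * l2_penalty(mm$params)
  }
  v0 <- beatfuse:::flatten_params(mod$params)
  set.seed(99)
  lg <- beatfuse:::model_loss_grads(mod, inp, y, "train")
  g_an <- beatfuse:::flatten_params(lg$grads)
  set.seed(18)
  pick <- sample(length(v0), 80)
  h <- 1e-6
  for (i in pick) {
    vp <- v0; vp[i] <- vp[i] + h
    vm <- v0; vm[i] <- vm[i] - h
    g_num <- (loss_at(vp) - loss_at(vm)) / (2 * h)
    denom <- max(abs(g_num), abs(g_an[i]), 1e-4)
    expect_lt(abs(g_num - g_an[i]) / denom, 1e-4)
  }
})

test_that("the training loss is exactly BCE plus the scaled penalty", {
  cfg <- tiny_cfg(n_classes = 2L)
  mod <- build_model("beatfusion", cfg, seed = 19)
  inp <- random_beat_input(cfg, 2, seed = 20)
  y <- matrix(c(1, 0, 0, 1), 2, 2)
  set.seed(99)
  lg <- beatfuse:::model_loss_grads(mod, inp, y, "train")
  expect_equal(lg$loss - lg$loss_bce,
               cfg$l2_weight * l2_penalty(mod$params), tolerance = 1e-12)
})

test_that("input validation names the offending dimension", {
  cfg <- tiny_cfg()
  m <- build_model("beatfusion", cfg, seed = 21)
  bad <- random_beat_input(tiny_cfg(), 2, seed = 22)
  bad$beats <- bad$beats[, , , 1:5, drop = FALSE]
  expect_error(model_forward(m, bad, "eval"), "L_b")
  expect_error(encode_beat_cnn(array(0, dim = c(2, 3, 8)), m), "expects")
})
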