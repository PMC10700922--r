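test_that("beat templates are deterministic and class perturbations are exact", {
  t1 <- make_beat_template("NORM", seed = 1)
  t2 <- make_beat_template("NORM", seed = 1)
  expect_identical(t1, t2)

  st <- make_beat_template("ST-shift", seed = 1, st_delta = 0.25)
  expect_equal(st$waves$amp[st$waves$component == "ST"], 0.25)
  # everything except the ST pedestal matches NORM at the same seed
  keep <- t1$waves$component != "ST"
  expect_equal(st$waves[keep, ], t1$waves[keep, ])

  wq <- make_beat_template("wide-QRS", seed = 7, qrs_widen = 1.8)
  nm <- make_beat_template("NORM", seed = 7)
  qrs <- nm$waves$component %in% c("Q", "R", "S")
  expect_equal(wq$waves$width[qrs], nm$waves$width[qrs] * 1.8)
  expect_true(all(wq$waves$width[qrs] > nm$waves$width[qrs]))
  expect_equal(wq$waves$amp[wq$waves$component == "R"],
               nm$waves$amp[nm$waves$component == "R"])

  np <- make_beat_template("no-P", seed = 2)
  expect_equal(np$waves$amp[np$waves$component == "P"], 0)

  expect_error(make_beat_template("VT"), "registry|NORM")
})

test_that("synthesized records have the expected beat count and determinism", {
  sp <- synth_spec(fs = 100, duration = 10, heart_rate = 72, rr_jitter = 0,
                   noise_sd = 0, baseline_wander_amp = 0, seed = 5)
  rec <- synthesize_record(sp)
  expect_equal(length(rec$rpeaks_true), 12)  # floor(10 * 72 / 60)
  expect_equal(nrow(rec$signal), 1000)
  expect_equal(ncol(rec$signal), 12)
  expect_identical(rec, synthesize_record(sp))

  noisy <- synth_spec(seed = 9, noise_sd = 0.08)
  expect_identical(synthesize_record(noisy), synthesize_record(noisy))

  expect_error(synthesize_record(synth_spec(duration = 0.5, heart_rate = 30)),
               "no complete beat")
  expect_error(synth_spec(rr_jitter = 0.6), "rr_jitter")
  expect_error(synth_spec(heart_rate = 10), "heart_rate")
})

test_that("noiseless records are the per-lead scaled template superposition", {
  rec <- synthesize_record(synth_spec(noise_sd = 0, baseline_wander_amp = 0,
                                      seed = 3))
  # every lead is the reference waveform times its fixed scaling
  scale <- make_beat_template("NORM", seed = 3)$lead_scale
  for (d in seq_len(12)) {
    expect_equal(rec$signal[, d], rec$signal[, 2] * scale[d],
                 tolerance = 1e-12)
  }
})

test_that("the true R-peak is the local amplitude maximum (noiseless)", {
  rec <- synthesize_record(synth_spec(noise_sd = 0, baseline_wander_amp = 0,
                                      rr_jitter = 0.05, seed = 11))
  half <- round(0.1 * rec$fs)
  for (r in rec$rpeaks_true) {
    lo <- max(1, r - half); hi <- min(nrow(rec$signal), r + half)
    expect_equal(lo + which.max(rec$signal[lo:hi, 2]) - 1, r)
  }
})

test_that("designated abnormal beats deviate from the others", {
  sp <- synth_spec(noise_sd = 0, baseline_wander_amp = 0, rr_jitter = 0,
                   class_label = "wide-QRS", abnormal_beat_indices = c(3, 7),
                   seed = 21)
  rec <- synthesize_record(sp)
  bs <- segment_record(rec, rec$rpeaks_true, segmentation_config())
  # distance of each beat to the pointwise median beat (the NORM shape)
  valid <- seq_len(bs$s_valid)
  med <- apply(bs$beats[valid, , ], c(2, 3), stats::median)
  d <- vapply(valid, function(i) sqrt(mean((bs$beats[i, , ] - med)^2)),
              numeric(1))
  expect_setequal(order(d, decreasing = TRUE)[1:2], c(3, 7))
  expect_equal(rec$abnormal_beats, c(3L, 7L))
})

test_that("dataset class mix is honoured and reproducible", {
  recs <- synthesize_dataset(100, c(NORM = 0.5, `ST-shift` = 0.5),
                             synth_spec(noise_sd = 0.02), seed = 31)
  lab <- attr(recs, "label_matrix")
  expect_equal(sum(lab[, "NORM"]), 50)
  expect_equal(sum(lab[, "ST-shift"]), 50)

  again <- synthesize_dataset(100, c(NORM = 0.5, `ST-shift` = 0.5),
                              synth_spec(noise_sd = 0.02), seed = 31)
  expect_identical(recs[[17]]$signal, again[[17]]$signal)

  # three classes at n = 600: every count within 1 of its quota
  task <- synth_task()
  lab600 <- attr(task$train, "label_matrix")
  counts <- colSums(lab600[, three_classes])
  quota <- 600 * three_class_mix
  expect_true(all(abs(counts - quota) <= 1))

  expect_error(synthesize_dataset(0, c(NORM = 1)), "positive")
  expect_error(synthesize_dataset(10, c(NORM = 0.7)), "sum to 1")
})

test_that("co-occurring abnormal tags produce multi-hot labels", {
  recs <- synthesize_dataset(10, c(`ST-shift+no-P` = 1),
                             synth_spec(noise_sd = 0.02), seed = 41)
  lab <- attr(recs, "label_matrix")
  expect_true(all(lab[, "ST-shift"] == 1))
  expect_true(all(lab[, "no-P"] == 1))
  expect_true(all(lab[, "NORM"] == 0))
})

test_that("noiseless classes are linearly separable on mean-beat features", {
  recs <- synthesize_dataset(
    30, c(NORM = 0.5, `wide-QRS` = 0.5),
    synth_spec(noise_sd = 0, baseline_wander_amp = 0), seed = 51
  )
  feats <- t(vapply(recs, function(r) {
    bs <- segment_record(r, r$rpeaks_true, segmentation_config())
    as.numeric(apply(bs$beats[seq_len(bs$s_valid), , ], c(2, 3), mean))
  }, numeric(12 * 80)))
  y <- attr(recs, "label_matrix")[, "wide-QRS"]
  # Fisher-style linear rule: project on the class-mean difference
  w <- colMeans(feats[y == 1, ]) - colMeans(feats[y == 0, ])
  s <- as.numeric(feats %*% w)
  thr <- (mean(s[y == 1]) + mean(s[y == 0])) / 2
  expect_equal(as.numeric(s > thr), as.numeric(y))
})
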