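# Fixtures built once per test run and cached.

.fixture_cache <- new.env(parent = emptyenv())

fixture <- function(name, builder) {
  if (!exists(name, envir = .fixture_cache)) {
    assign(name, builder(), envir = .fixture_cache)
  }
  get(name, envir = .fixture_cache)
}

three_class_mix <- c(NORM = 0.34, `ST-shift` = 0.33, `wide-QRS` = 0.33)
three_classes <- c("NORM", "ST-shift", "wide-QRS")

# The scaled-down 3-class study task: 600 train / 200 test records at 20 dB
# SNR, every beat of an abnormal record abnormal.
synth_task <- function() {
  fixture("synth_task", function() {
    list(
      train = synthesize_dataset(600, three_class_mix,
                                 synth_spec(snr_db = 20), seed = 101L),
      test = synthesize_dataset(200, three_class_mix,
                                synth_spec(snr_db = 20), seed = 202L)
    )
  })
}

# Segmented (full-pipeline: detected peaks) model data for the study task.
synth_task_data <- function(variant = "beatfusion") {
  fixture(paste0("synth_task_data_", variant), function() {
    task <- synth_task()
    tr <- model_data(task$train, variant)
    te <- model_data(task$test, variant)
    tr$y <- tr$y[, three_classes]
    te$y <- te$y[, three_classes]
    list(train = tr, test = te)
  })
}

# A tiny model configuration for structural tests (not for learning).
tiny_cfg <- function(n_classes = 2L) {
  model_config(D = 2L, L_b = 8L, S_max = 4L, conv_channels = c(3L, 4L),
               conv_strides = c(2L, 1L), kernel_size = 3L,
               dropout_rate = 0.2, gru_hidden = 3L, per_step_width = 2L,
               attn_dim = 3L, clf_hidden = 4L, n_classes = n_classes,
               l2_weight = 1e-3, record_len = 16L)
}

random_beat_input <- function(cfg, n, seed = 1) {
  set.seed(seed)
  S <- cfg$S_max
  beats <- array(rnorm(n * S * cfg$D * cfg$L_b), dim = c(n, S, cfg$D, cfg$L_b))
  mask <- t(vapply(seq_len(n), function(i) {
    s <- sample(seq_len(S), 1)
    c(rep(1L, s), rep(0L, S - s))
  }, integer(S)))
  for (i in seq_len(n)) {
    for (s in seq_len(S)) if (mask[i, s] == 0) beats[i, s, , ] <- 0
  }
  list(beats = beats, mask = mask)
}

# Miniature synthetic PTB-XL-style directory (labelled synthetic throughout),
# written to a temporary path: 6 records, 5 statement codes.
write_synthetic_ptbxl <- function(root) {
  dir.create(file.path(root, "records100", "00000"), recursive = TRUE,
             showWarnings = FALSE)
  statements <- data.frame(
    code = c("NORM", "IMI", "ASMI", "NDT", "SR"),
    description = c("normal", "inferior MI", "anteroseptal MI",
                    "non-diagnostic T", "sinus rhythm"),
    diagnostic = c(1, 1, 1, 1, NA),
    form = c(NA, NA, NA, 1, NA),
    rhythm = c(NA, NA, NA, NA, 1),
    diagnostic_class = c("NORM", "MI", "MI", "STTC", ""),
    diagnostic_subclass = c("NORM", "IMI", "AMI", "STTC", "")
  )
  write.csv(statements, file.path(root, "scp_statements.csv"),
            row.names = FALSE)
  scp <- c("{'NORM': 100.0, 'SR': 0.0}",
           "{'IMI': 100.0}",
           "{'IMI': 80.0, 'ASMI': 50.0}",
           "{'NDT': 100.0, 'SR': 0.0}",
           "{'NORM': 100.0}",
           "{'ASMI': 100.0, 'NDT': 35.0}")
  db <- data.frame(
    ecg_id = 1:6,
    scp_codes = scp,
    strat_fold = c(1, 2, 10, 9, 10, 3),
    filename_lr = sprintf("records100/00000/%05d_lr", 1:6)
  )
  write.csv(db, file.path(root, "ptbxl_database.csv"), row.names = FALSE)
  for (i in 1:6) {
    rec <- synthesize_record(synth_spec(duration = 4, seed = i,
                                        noise_sd = 0.02,
                                        baseline_wander_amp = 0))
    write_wfdb(rec, file.path(root, db$filename_lr[i]))
  }
  root
}
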