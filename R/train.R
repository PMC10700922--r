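# Training: Adam optimization of BCE + L2, early stopping on validation
# macro-AUC, cross-validation ensembling, and the beat-length sweep driver.

#' Training configuration
#'
#' @param batch_size Records per mini-batch (256 in the reference setting;
#'   smaller values suit desk-scale runs).
#' @param learning_rate Adam step size (reference 3e-4).
#' @param epochs Maximum epochs.
#' @param folds Number of cross-validation rotations (reference 9).
#' @param seed Integer seed; fixes shuffling, dropout and initialization.
#' @param l2_weight Optional override of the model's L2 coefficient.
#' @param early_stop_patience Epochs without validation macro-AUC improvement
#'   before stopping (ignored when no validation set is given).
#' @return An object of class `train_config`.
#' @export
train_config <- function(batch_size = 256L, learning_rate = 3e-4,
                         epochs = 50L, folds = 9L, seed = 1L,
                         l2_weight = NULL, early_stop_patience = 10L) {
  if (batch_size < 1) stopf("batch_size must be >= 1")
  if (learning_rate < 0) stopf("learning_rate must be non-negative")
  if (folds < 2) stopf("folds must be >= 2")
  structure(
    list(batch_size = as.integer(batch_size),
         learning_rate = learning_rate, epochs = as.integer(epochs),
         folds = as.integer(folds), seed = as.integer(seed),
         l2_weight = l2_weight,
         early_stop_patience = as.integer(early_stop_patience)),
    class = "train_config"
  )
}

# ---- dataset plumbing ----------------------------------------------------

#' Assemble model-ready data
#'
#' @param records List of `ecg_record`s.
#' @param variant Model variant the data is for.
#' @param scfg,dcfg Segmentation and detector configurations (beat-fusion
#'   variant).
#' @param peaks `"detect"` (full pipeline) or `"true"` (generator ground
#'   truth).
#' @return List with `x` (beats+mask list, or record array) and `y` (label
#'   matrix).
#' @export
model_data <- function(records, variant = "beatfusion",
                       scfg = segmentation_config(),
                       dcfg = detector_config(), peaks = "detect") {
  if (variant == "beatfusion") {
    pd <- prepare_beat_data(records, scfg, peaks, dcfg)
    list(x = list(beats = pd$beats, mask = pd$mask), y = pd$labels)
  } else {
    labels <- attr(records, "label_matrix")
    if (is.null(labels)) {
      labels <- t(vapply(records, function(r) as.numeric(r$labels),
                         numeric(length(records[[1]]$labels))))
      colnames(labels) <- names(records[[1]]$labels)
    }
    list(x = record_array(records), y = labels)
  }
}

data_size <- function(data) nrow(data$y)

slice_data <- function(data, idx) {
  if (is.list(data$x)) {
    list(x = list(beats = data$x$beats[idx, , , , drop = FALSE],
                  mask = data$x$mask[idx, , drop = FALSE]),
         y = data$y[idx, , drop = FALSE])
  } else {
    list(x = data$x[idx, , , drop = FALSE],
         y = data$y[idx, , drop = FALSE])
  }
}

#' Predict class probabilities
#'
#' @param model A trained `ecg_model`.
#' @param data A [model_data()] list (labels may be absent).
#' @param chunk Records per forward pass.
#' @return `n x n_classes` probability matrix.
#' @export
predict_probs <- function(model, data, chunk = 128L) {
  n <- if (is.list(data$x)) dim(data$x$beats)[1] else dim(data$x)[1]
  out <- matrix(NA_real_, n, model$cfg$n_classes)
  for (start in seq(1L, n, by = chunk)) {
    idx <- start:min(n, start + chunk - 1L)
    sl <- slice_data(list(x = data$x,
                          y = if (is.null(data$y))
                            matrix(0, n, model$cfg$n_classes) else data$y),
                     idx)
    out[idx, ] <- model_forward(model, sl$x, "eval")$probs
  }
  colnames(out) <- colnames(data$y)
  out
}

# ---- Adam ----------------------------------------------------------------

adam_init <- function(params) {
  zeros <- tree_map(function(a) array(0, dim = if (is.null(dim(a)))
    length(a) else dim(a)), params)
  list(m = zeros, v = zeros, t = 0L)
}

adam_step <- function(params, grads, state, lr, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8) {
  state$t <- state$t + 1L
  state$m <- tree_map(function(m, g) beta1 * m + (1 - beta1) * g,
                      state$m, grads)
  state$v <- tree_map(function(v, g) beta2 * v + (1 - beta2) * g * g,
                      state$v, grads)
  c1 <- 1 - beta1^state$t
  c2 <- 1 - beta2^state$t
  params <- tree_map(function(p, m, v) {
    upd <- p - lr * (m / c1) / (sqrt(v / c2) + eps)
    dim(upd) <- dim(p)
    upd
  }, params, state$m, state$v)
  list(params = params, state = state)
}

# ---- fit -----------------------------------------------------------------

#' Train a model
#'
#' Minimizes BCE + `l2_weight * sum(weights^2)` with Adam on shuffled
#' mini-batches.  When a validation set is supplied, logs validation
#' macro-AUC per epoch and stops early after `early_stop_patience` epochs
#' without improvement, restoring the best parameters.  Fully seeded.
#'
#' @param model An `ecg_model` from [build_model()].
#' @param data Training data from [model_data()].
#' @param tcfg A [train_config()].
#' @param val_data Optional validation data.
#' @param verbose Print per-epoch progress.
#' @return The trained model, with a `history` element (data frame of epoch,
#'   train loss, validation macro-AUC).
#' @export
fit <- function(model, data, tcfg = train_config(), val_data = NULL,
                verbose = FALSE) {
  n <- data_size(data)
  if (n == 0) stopf("empty training set")
  if (!is.null(tcfg$l2_weight)) model$cfg$l2_weight <- tcfg$l2_weight
  opt <- adam_init(model$params)
  best_auc <- -Inf
  best_params <- NULL
  best_buffers <- NULL
  wait <- 0L
  hist <- data.frame(epoch = integer(0), train_loss = numeric(0),
                     val_macro_auc = numeric(0))

  set.seed(tcfg$seed)
  for (epoch in seq_len(tcfg$epochs)) {
    ord <- sample.int(n)
    losses <- numeric(0)
    for (start in seq(1L, n, by = tcfg$batch_size)) {
      idx <- ord[start:min(n, start + tcfg$batch_size - 1L)]
      batch <- slice_data(data, idx)
      lg <- model_loss_grads(model, batch$x, batch$y, "train")
      model$buffers <- lg$buffers
      if (tcfg$learning_rate > 0) {
        st <- adam_step(model$params, lg$grads, opt, tcfg$learning_rate)
        model$params <- st$params
        opt <- st$state
      }
      losses <- c(losses, lg$loss)
    }
    val_auc <- NA_real_
    if (!is.null(val_data)) {
      vp <- predict_probs(model, val_data)
      val_auc <- suppressWarnings(as.numeric(macro_auc(vp, val_data$y)))
      if (val_auc > best_auc + 1e-6) {
        best_auc <- val_auc
        best_params <- model$params
        best_buffers <- model$buffers
        wait <- 0L
      } else {
        wait <- wait + 1L
      }
    }
    hist <- rbind(hist, data.frame(epoch = epoch,
                                   train_loss = mean(losses),
                                   val_macro_auc = val_auc))
    if (verbose) {
      message(sprintf("epoch %3d  loss %.4f  val macro-AUC %s", epoch,
                      mean(losses),
                      if (is.na(val_auc)) "-" else sprintf("%.4f", val_auc)))
    }
    if (!is.null(val_data) && wait >= tcfg$early_stop_patience) break
  }
  if (!is.null(best_params)) {
    model$params <- best_params
    model$buffers <- best_buffers
  }
  model$history <- hist
  model
}

# ---- cross-validation ensemble ------------------------------------------

#' Cross-validation ensemble
#'
#' Splits the data into `folds + 1` equal parts: the last part is the
#' held-out test set; each of the remaining `folds` parts takes one turn as
#' the validation fold while a model trains on the others.  Test
#' probabilities are the arithmetic mean of the fold models' sigmoid
#' outputs.
#'
#' @param data Data from [model_data()].
#' @param tcfg A [train_config()]; `tcfg$folds` models are trained.
#' @param cfg A [model_config()].
#' @param variant Model variant.
#' @param fold_id Optional integer vector in `1..(folds + 1)` assigning each
#'   record to a part (part `folds + 1` is the test set); a seeded balanced
#'   assignment is drawn when `NULL`.
#' @return List with `probs` (ensemble test probabilities), `truth`,
#'   `test_idx`, `macro_auc`, `models`.
#' @export
cross_validate_ensemble <- function(data, tcfg, cfg, variant = "beatfusion",
                                    fold_id = NULL) {
  n <- data_size(data)
  parts <- tcfg$folds + 1L
  if (is.null(fold_id)) {
    fold_id <- with_seed(tcfg$seed, sample(rep_len(seq_len(parts), n)))
  }
  if (any(tabulate(fold_id, parts) == 0)) {
    stopf("every fold must contain at least one record")
  }
  test_idx <- which(fold_id == parts)
  test <- slice_data(data, test_idx)
  models <- vector("list", tcfg$folds)
  prob_sum <- 0
  seeds <- derive_seeds(tcfg$seed, tcfg$folds)
  for (k in seq_len(tcfg$folds)) {
    tr_idx <- which(fold_id != parts & fold_id != k)
    va_idx <- which(fold_id == k)
    tk <- tcfg
    tk$seed <- seeds[k]
    m <- build_model(variant, cfg, seed = seeds[k])
    m <- fit(m, slice_data(data, tr_idx), tk,
             val_data = slice_data(data, va_idx))
    models[[k]] <- m
    prob_sum <- prob_sum + predict_probs(m, test)
  }
  probs <- prob_sum / tcfg$folds
  mac <- suppressWarnings(as.numeric(macro_auc(probs, test$y)))
  list(probs = probs, truth = test$y, test_idx = test_idx,
       macro_auc = mac, models = models)
}

# ---- beat-length sweep ---------------------------------------------------

#' Beat-window length for a given split ratio
#'
#' Keeps the reference 25:55 before/after split, rounded to integers.
#'
#' @param L_b Total beat length.
#' @return List with `L_f` and `L_k` (`L_f + L_k = L_b`).
#' @export
beat_window_split <- function(L_b) {
  L_f <- round(L_b * 25 / 80)
  list(L_f = as.integer(L_f), L_k = as.integer(L_b - L_f))
}

#' Sweep the beat-window length
#'
#' Re-segments the records at each requested beat length (before/after split
#' per [beat_window_split()]), trains a beat-fusion model per length, and
#' reports held-out macro-AUC.
#'
#' @param train_records,test_records Record lists.
#' @param lengths Beat lengths in samples; each must be divisible by the
#'   model's stride product.
#' @param tcfg A [train_config()].
#' @param cfg_base A [model_config()] whose `L_b` is replaced per length.
#' @param dcfg Detector configuration.
#' @param peaks Passed to [model_data()].
#' @return Data frame with one row per length: `L_b`, `L_f`, `L_k`,
#'   `macro_auc`.
#' @export
run_beat_length_sweep <- function(train_records, test_records, lengths,
                                  tcfg = train_config(),
                                  cfg_base = small_model_config(),
                                  dcfg = detector_config(),
                                  peaks = "detect") {
  sp <- prod(cfg_base$conv_strides)
  rows <- lapply(lengths, function(len) {
    if (len %% sp != 0) {
      stopf("beat length %d is not divisible by the stride product %d",
            len, sp)
    }
    w <- beat_window_split(len)
    scfg <- segmentation_config(w$L_f, w$L_k, cfg_base$S_max)
    cfg <- cfg_base
    cfg$L_b <- as.integer(len)
    cfg$T_beat <- len %/% sp
    cfg$beat_feature_dim <- cfg$per_step_width * cfg$T_beat
    tr <- model_data(train_records, "beatfusion", scfg, dcfg, peaks)
    te <- model_data(test_records, "beatfusion", scfg, dcfg, peaks)
    cfg$n_classes <- ncol(tr$y)
    m <- build_model("beatfusion", cfg, seed = tcfg$seed)
    m <- fit(m, tr, tcfg, val_data = te)
    mac <- suppressWarnings(as.numeric(macro_auc(predict_probs(m, te),
                                                 te$y)))
    data.frame(L_b = len, L_f = w$L_f, L_k = w$L_k, macro_auc = mac)
  })
  do.call(rbind, rows)
}

# ---- attention export ----------------------------------------------------

#' Export per-beat attention weights for one record
#'
#' Runs the full pipeline (detection, segmentation, forward pass) on one
#' record and returns the attention weight assigned to each detected beat,
#' aligned with its window start sample.
#'
#' @param model A trained beat-fusion `ecg_model`.
#' @param record An `ecg_record`.
#' @param dcfg,scfg Detector and segmentation configurations.
#' @param peaks `"detect"` or `"true"`.
#' @return Data frame with `beat_index`, `peak_sample`, `start_sample`,
#'   `weight`.
#' @export
export_attention <- function(model, record, dcfg = detector_config(),
                             scfg = segmentation_config(),
                             peaks = "detect") {
  if (model$variant != "beatfusion") {
    stopf("attention export requires the beat-fusion variant")
  }
  p <- if (peaks == "true") record$rpeaks_true
       else detect_rpeaks(record, dcfg)$indices
  bs <- segment_record(record, p, scfg)
  input <- list(
    beats = array(bs$beats, dim = c(1L, dim(bs$beats))),
    mask = matrix(bs$mask, nrow = 1)
  )
  fw <- model_forward(model, input, "eval")
  used <- bs$peaks_used
  data.frame(beat_index = seq_along(used), peak_sample = used,
             start_sample = used - scfg$L_f,
             weight = fw$alpha[1, seq_along(used)])
}
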