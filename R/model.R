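# Beat-level fusion model: shared CNN + bidirectional GRU beat encoder,
# masked attention fusion across beats, and a two-layer sigmoid multilabel
# classifier; plus the two ablation variants (plain backbone on the
# unsegmented record, and temporal attention over encoder time steps).

#' Model configuration
#'
#' The reference configuration encodes 80-sample, 12-lead beats with a
#' six-layer 1-D convolution stack (channels 64-64-128-128-256-256, kernel 3,
#' strides 2-1-2-1-2-1, batch norm + ReLU after each layer, dropout after
#' every second layer), reducing each beat to a 256 x 10 feature map; a
#' bidirectional GRU (64 units per direction) plus a shared per-step linear
#' layer turn that into 10 steps of 64 features, flattened to a 640-feature
#' beat vector.  Attention dimension 55 and classifier hidden width 25 with a
#' 23-class head complete the reference model at exactly 569373 trainable
#' parameters (see `scripts/resolve_budget.R` for the search that fixes the
#' two free widths against that budget).
#'
#' @param D Number of leads.
#' @param L_b Beat length in samples; must be divisible by the product of
#'   `conv_strides`.
#' @param S_max Beat slots per record.
#' @param conv_channels,conv_strides Integer vectors, one entry per
#'   convolution layer.
#' @param kernel_size Odd convolution kernel width.
#' @param dropout_rate Dropout probability (applied after every second
#'   convolution layer, training mode only).
#' @param gru_hidden GRU width per direction.
#' @param per_step_width Output width of the shared per-step linear layer.
#' @param attn_dim Attention projection dimension.
#' @param clf_hidden Classifier hidden width.
#' @param n_classes Number of output classes.
#' @param l2_weight Coefficient of the explicit L2 penalty in the training
#'   loss.
#' @param record_len Record length in samples (used by the unsegmented
#'   ablation variants); must be divisible by the stride product.
#' @return An object of class `model_config`.
#' @export
model_config <- function(D = 12L, L_b = 80L, S_max = 20L,
                         conv_channels = c(64L, 64L, 128L, 128L, 256L, 256L),
                         conv_strides = c(2L, 1L, 2L, 1L, 2L, 1L),
                         kernel_size = 3L, dropout_rate = 0.2,
                         gru_hidden = 64L, per_step_width = 64L,
                         attn_dim = 55L, clf_hidden = 25L, n_classes = 23L,
                         l2_weight = 1e-4, record_len = 1000L) {
  if (length(conv_channels) != length(conv_strides)) {
    stopf("conv_channels and conv_strides must have the same length")
  }
  if (kernel_size %% 2 != 1) stopf("kernel_size must be odd")
  sp <- prod(conv_strides)
  if (L_b %% sp != 0) {
    stopf("L_b (%d) must be divisible by the stride product (%d)", L_b, sp)
  }
  if (record_len %% sp != 0) {
    stopf("record_len (%d) must be divisible by the stride product (%d)",
          record_len, sp)
  }
  cfg <- structure(
    list(D = as.integer(D), L_b = as.integer(L_b), S_max = as.integer(S_max),
         conv_channels = as.integer(conv_channels),
         conv_strides = as.integer(conv_strides),
         kernel_size = as.integer(kernel_size), dropout_rate = dropout_rate,
         gru_hidden = as.integer(gru_hidden),
         per_step_width = as.integer(per_step_width),
         attn_dim = as.integer(attn_dim), clf_hidden = as.integer(clf_hidden),
         n_classes = as.integer(n_classes), l2_weight = l2_weight,
         record_len = as.integer(record_len)),
    class = "model_config"
  )
  cfg$stride_prod <- sp
  cfg$T_beat <- cfg$L_b %/% sp
  cfg$beat_feature_dim <- cfg$per_step_width * cfg$T_beat
  cfg
}

#' A small configuration for desk-scale experiments
#'
#' Same topology as [model_config()] with narrow layers (channels 8-8-16-16-
#' 32-32, GRU 16, 160-feature beats), suitable for CPU training on synthetic
#' data.
#'
#' @param n_classes Number of output classes.
#' @param ... Overrides passed to [model_config()].
#' @export
small_model_config <- function(n_classes = 3L, ...) {
  model_config(conv_channels = c(8L, 8L, 16L, 16L, 32L, 32L),
               gru_hidden = 16L, per_step_width = 16L, attn_dim = 16L,
               clf_hidden = 32L, n_classes = n_classes, ...)
}

# ---- initialization ------------------------------------------------------

xavier_uniform <- function(nr, nc, fan_in, fan_out) {
  lim <- sqrt(6 / (fan_in + fan_out))
  matrix(stats::runif(nr * nc, -lim, lim), nr, nc)
}

orthogonal_init <- function(nr, nc) {
  if (nr >= nc) {
    a <- matrix(stats::rnorm(nr * nc), nr, nc)
    qr.Q(qr(a))[, seq_len(nc), drop = FALSE]
  } else {
    a <- matrix(stats::rnorm(nc * nr), nc, nr)
    t(qr.Q(qr(a))[, seq_len(nr), drop = FALSE])
  }
}

gru_dir_init <- function(input_w, g) {
  list(Wz = orthogonal_init(g, input_w), Uz = orthogonal_init(g, g),
       bz = numeric(g),
       Wr = orthogonal_init(g, input_w), Ur = orthogonal_init(g, g),
       br = numeric(g),
       Wh = orthogonal_init(g, input_w), Uh = orthogonal_init(g, g),
       bh = numeric(g))
}

#' Initialize model parameters
#'
#' Convolution and linear weights use the Xavier uniform initializer; GRU
#' input and recurrent weights use the orthogonal initializer (per gate
#' block); biases start at zero, batch-norm scale/shift at one/zero.
#' Deterministic for a fixed seed.
#'
#' @param cfg A [model_config()].
#' @param variant One of `"beatfusion"`, `"backbone"`,
#'   `"temporal_attention"`.
#' @param seed Integer seed.
#' @return Nested list of parameter arrays.
#' @export
init_params <- function(cfg, variant = "beatfusion", seed = 1L) {
  k <- cfg$kernel_size
  with_seed(seed, {
    n_layers <- length(cfg$conv_channels)
    conv <- vector("list", n_layers)
    bn <- vector("list", n_layers)
    c_in <- cfg$D
    for (l in seq_len(n_layers)) {
      c_out <- cfg$conv_channels[l]
      conv[[l]] <- list(
        W = xavier_uniform(c_out, k * c_in, fan_in = c_in * k,
                           fan_out = c_out * k),
        b = numeric(c_out)
      )
      bn[[l]] <- list(gamma = rep(1, c_out), beta = numeric(c_out))
      c_in <- c_out
    }
    g <- cfg$gru_hidden
    gru <- list(fwd = gru_dir_init(c_in, g), bwd = gru_dir_init(c_in, g))
    w <- cfg$per_step_width
    step_lin <- list(
      W = xavier_uniform(w, 2 * g, fan_in = 2 * g, fan_out = w),
      b = numeric(w)
    )
    clf_in <- switch(variant,
      beatfusion = cfg$beat_feature_dim,
      backbone = cfg$per_step_width * (cfg$record_len %/% cfg$stride_prod),
      temporal_attention = cfg$per_step_width,
      stopf("unknown variant '%s'", variant)
    )
    params <- list(conv = conv, bn = bn, gru = gru, step_lin = step_lin)
    if (variant %in% c("beatfusion", "temporal_attention")) {
      attn_in <- if (variant == "beatfusion") cfg$beat_feature_dim
                 else cfg$per_step_width
      a <- cfg$attn_dim
      params$attn <- list(
        W = xavier_uniform(a, attn_in, fan_in = attn_in, fan_out = a),
        b = numeric(a),
        u = as.numeric(xavier_uniform(a, 1, fan_in = a, fan_out = 1))
      )
    }
    h <- cfg$clf_hidden
    params$clf1 <- list(
      W = xavier_uniform(h, clf_in, fan_in = clf_in, fan_out = h),
      b = numeric(h)
    )
    params$clf2 <- list(
      W = xavier_uniform(cfg$n_classes, h, fan_in = h,
                         fan_out = cfg$n_classes),
      b = numeric(cfg$n_classes)
    )
    params
  })
}

#' Build a model variant
#'
#' `"beatfusion"` is the full pipeline (per-beat encoder, masked attention
#' fusion, classifier); `"backbone"` applies the same CNN + GRU encoder to
#' the whole unsegmented record followed directly by the classifier;
#' `"temporal_attention"` applies the attention operator across the time
#' steps of the unsegmented encoder output instead of across beats.
#'
#' @param variant Variant name.
#' @param cfg A [model_config()].
#' @param seed Seed for [init_params()].
#' @return An object of class `ecg_model`: list with `variant`, `cfg`,
#'   `params`, `buffers` (batch-norm running statistics).
#' @export
build_model <- function(variant = c("beatfusion", "backbone",
                                    "temporal_attention"),
                        cfg = model_config(), seed = 1L) {
  variant <- match.arg(variant)
  params <- init_params(cfg, variant, seed)
  buffers <- lapply(cfg$conv_channels, function(c_out) {
    list(mean = numeric(c_out), var = rep(1, c_out))
  })
  structure(list(variant = variant, cfg = cfg, params = params,
                 buffers = buffers),
            class = "ecg_model")
}

#' @export
print.ecg_model <- function(x, ...) {
  cat(sprintf("<ecg_model> variant '%s', %d classes, %d trainable parameters\n",
              x$variant, x$cfg$n_classes, count_parameters(x)))
  invisible(x)
}

#' Count trainable parameters
#'
#' @param model An `ecg_model` (batch-norm running statistics are buffers,
#'   not parameters, and are not counted).
#' @return Integer count of trainable scalars.
#' @export
count_parameters <- function(model) {
  length(flatten_params(model$params))
}

# ---- encoder (shared by all variants) ------------------------------------

# X: D x (L*nb).  Returns per-step features (list of T_ matrices w x nb),
# the layer caches, and updated batch-norm buffers.
encoder_fwd <- function(X, L, nb, model, mode) {
  cfg <- model$cfg
  p <- model$params
  buf <- model$buffers
  cur <- X
  Lc <- L
  n_layers <- length(cfg$conv_channels)
  caches <- vector("list", n_layers)
  for (l in seq_len(n_layers)) {
    cv <- conv1d_fwd(cur, p$conv[[l]]$W, p$conv[[l]]$b, Lc, nb,
                     cfg$conv_strides[l], cfg$kernel_size)
    Lc <- Lc %/% cfg$conv_strides[l]
    bnr <- bn_fwd(cv$out, p$bn[[l]]$gamma, p$bn[[l]]$beta,
                  buf[[l]]$mean, buf[[l]]$var, mode)
    buf[[l]] <- list(mean = bnr$rmean, var = bnr$rvar)
    rl <- relu_fwd(bnr$out)
    if (l %% 2 == 0) {
      dp <- dropout_fwd(rl$out, cfg$dropout_rate, mode)
      cur <- dp$out
      drop_cache <- dp$cache
    } else {
      cur <- rl$out
      drop_cache <- NULL
    }
    caches[[l]] <- list(conv = cv$cache, bn = bnr$cache, relu = rl$cache,
                        drop = drop_cache)
  }
  T_ <- Lc
  step_idx <- lapply(seq_len(T_), function(t) (0:(nb - 1L)) * T_ + t)
  Xsteps <- lapply(step_idx, function(ix) cur[, ix, drop = FALSE])
  gf <- gru_dir_fwd(Xsteps, p$gru$fwd)
  gb <- gru_dir_fwd(rev(Xsteps), p$gru$bwd)
  Hc <- vector("list", T_)
  steps <- vector("list", T_)
  for (t in seq_len(T_)) {
    Hc[[t]] <- rbind(gf$H[[t]], gb$H[[T_ + 1L - t]])
    steps[[t]] <- p$step_lin$W %*% Hc[[t]] + p$step_lin$b
  }
  list(steps = steps, T_ = T_, nb = nb,
       cache = list(conv = caches, gru_f = gf$cache, gru_b = gb$cache,
                    Hc = Hc, step_idx = step_idx, T_ = T_, nb = nb,
                    C_last = cfg$conv_channels[n_layers]),
       buffers = buf)
}

# dsteps: list of T_ gradients (w x nb) w.r.t. the per-step features.
encoder_bwd <- function(dsteps, cache, model, mode) {
  cfg <- model$cfg
  p <- model$params
  T_ <- cache$T_
  nb <- cache$nb
  g <- cfg$gru_hidden

  dW_lin <- array(0, dim = dim(p$step_lin$W))
  db_lin <- numeric(length(p$step_lin$b))
  dH_f <- vector("list", T_)
  dH_b_rev <- vector("list", T_)
  dHc <- vector("list", T_)
  for (t in seq_len(T_)) {
    dW_lin <- dW_lin + dsteps[[t]] %*% t(cache$Hc[[t]])
    db_lin <- db_lin + rowSums(dsteps[[t]])
    dHc[[t]] <- crossprod(p$step_lin$W, dsteps[[t]])
  }
  for (t in seq_len(T_)) {
    dH_f[[t]] <- dHc[[t]][seq_len(g), , drop = FALSE]
    dH_b_rev[[t]] <- dHc[[T_ + 1L - t]][g + seq_len(g), , drop = FALSE]
  }
  gbf <- gru_dir_bwd(dH_f, cache$gru_f, p$gru$fwd)
  gbb <- gru_dir_bwd(dH_b_rev, cache$gru_b, p$gru$bwd)

  dConv <- matrix(0, cache$C_last, T_ * nb)
  for (t in seq_len(T_)) {
    dConv[, cache$step_idx[[t]]] <- gbf$dX[[t]] + gbb$dX[[T_ + 1L - t]]
  }

  n_layers <- length(cfg$conv_channels)
  dconv <- vector("list", n_layers)
  dbn <- vector("list", n_layers)
  cur <- dConv
  for (l in rev(seq_len(n_layers))) {
    ca <- cache$conv[[l]]
    if (l %% 2 == 0) cur <- dropout_bwd(cur, ca$drop)
    cur <- relu_bwd(cur, ca$relu)
    bb <- bn_bwd(cur, p$bn[[l]]$gamma, ca$bn)
    dbn[[l]] <- list(gamma = bb$dgamma, beta = bb$dbeta)
    cb <- conv1d_bwd(bb$dX, p$conv[[l]]$W, ca$conv)
    dconv[[l]] <- list(W = cb$dW, b = cb$db)
    cur <- cb$dX
  }
  list(conv = dconv, bn = dbn,
       gru = list(fwd = gbf$grads, bwd = gbb$grads),
       step_lin = list(W = dW_lin, b = db_lin))
}

# Stack per-step features into per-sequence feature vectors:
# F[(t-1)*w + (1:w), b] = steps[[t]][, b].
stack_steps <- function(steps) {
  w <- nrow(steps[[1]])
  T_ <- length(steps)
  F_ <- matrix(0, w * T_, ncol(steps[[1]]))
  for (t in seq_len(T_)) F_[(t - 1L) * w + seq_len(w), ] <- steps[[t]]
  F_
}

unstack_steps <- function(F_, w, T_) {
  lapply(seq_len(T_), function(t) F_[(t - 1L) * w + seq_len(w), ,
                                     drop = FALSE])
}

# ---- full forward / backward --------------------------------------------

#' Run a model forward
#'
#' @param model An `ecg_model` from [build_model()].
#' @param input For the `"beatfusion"` variant, a list with `beats`
#'   (`n x S x D x L_b` array) and `mask` (`n x S`), e.g. from
#'   [prepare_beat_data()]; for the unsegmented variants, an `n x D x L`
#'   array of records (see [record_array()]).
#' @param mode `"eval"` (deterministic: no dropout, batch norm uses running
#'   statistics) or `"train"`.
#' @return List with `probs` (`n x n_classes`, all entries in (0, 1)),
#'   `alpha` (attention weights: `n x S_max` for beat fusion, `n x T` for
#'   temporal attention, `NULL` for the backbone), and internal `cache` /
#'   `buffers` used by the training loop.
#' @export
model_forward <- function(model, input, mode = c("eval", "train")) {
  mode <- match.arg(mode)
  cfg <- model$cfg
  p <- model$params

  if (model$variant == "beatfusion") {
    beats <- input$beats
    mask <- input$mask
    if (is.null(beats) || is.null(mask)) {
      stopf("beat-fusion input must be a list with 'beats' and 'mask'")
    }
    dims <- dim(beats)
    if (length(dims) != 4 || dims[3] != cfg$D || dims[4] != cfg$L_b) {
      stopf("beats must be n x S x D x L_b = n x %d x %d x %d",
            cfg$S_max, cfg$D, cfg$L_b)
    }
    n <- dims[1]; S <- dims[2]
    M <- matrix(aperm(beats, c(3, 4, 2, 1)), nrow = cfg$D)
    maskvec <- as.numeric(t(mask))
    vslots <- which(maskvec == 1)
    if (length(vslots) == 0) stopf("no valid beats in the batch")
    cols <- rep((vslots - 1L) * cfg$L_b, each = cfg$L_b) +
      rep(seq_len(cfg$L_b), length(vslots))
    Xv <- M[, cols, drop = FALSE]
    enc <- encoder_fwd(Xv, cfg$L_b, length(vslots), model, mode)
    Fv <- stack_steps(enc$steps)
    Feat <- matrix(0, nrow(Fv), S * n)
    Feat[, vslots] <- Fv
    at <- attention_fwd(Feat, maskvec, S, n, p$attn)
    feat_in <- at$f_att
    alpha <- t(at$alpha)
  } else {
    if (length(dim(input)) != 3) stopf("unsegmented input must be n x D x L")
    n <- dim(input)[1]
    L <- dim(input)[3]
    X <- matrix(aperm(input, c(2, 3, 1)), nrow = dim(input)[2])
    enc <- encoder_fwd(X, L, n, model, mode)
    if (model$variant == "backbone") {
      feat_in <- stack_steps(enc$steps)
      at <- NULL
      alpha <- NULL
    } else {  # temporal_attention
      T_ <- enc$T_
      Feat <- matrix(0, cfg$per_step_width, T_ * n)
      for (t in seq_len(T_)) {
        Feat[, (0:(n - 1L)) * T_ + t] <- enc$steps[[t]]
      }
      at <- attention_fwd(Feat, rep(1, T_ * n), T_, n, p$attn)
      feat_in <- at$f_att
      alpha <- t(at$alpha)
    }
  }

  l1 <- linear_fwd(feat_in, p$clf1$W, p$clf1$b)
  r1 <- relu_fwd(l1$out)
  l2 <- linear_fwd(r1$out, p$clf2$W, p$clf2$b)
  probs <- sigmoid(l2$out)  # n_classes x n

  list(probs = t(probs), alpha = alpha,
       cache = list(enc = enc$cache, attn = if (!is.null(at)) at$cache,
                    clf1 = l1$cache, relu1 = r1$cache, clf2 = l2$cache,
                    vslots = if (model$variant == "beatfusion") vslots,
                    S = if (model$variant == "beatfusion") dim(input$mask)[2],
                    n = n, probs_t = probs),
       buffers = enc$buffers)
}

# dlogits: n_classes x n gradient at the classifier output (pre-sigmoid).
model_backward <- function(model, cache, dlogits) {
  cfg <- model$cfg
  p <- model$params
  lb2 <- linear_bwd(dlogits, p$clf2$W, cache$clf2)
  dr1 <- relu_bwd(lb2$dX, cache$relu1)
  lb1 <- linear_bwd(dr1, p$clf1$W, cache$clf1)
  dfeat <- lb1$dX

  grads <- list()
  if (model$variant == "beatfusion") {
    ab <- attention_bwd(dfeat, cache$attn, p$attn)
    dFv <- ab$dFeat[, cache$vslots, drop = FALSE]
    dsteps <- unstack_steps(dFv, cfg$per_step_width, cache$enc$T_)
    enc_g <- encoder_bwd(dsteps, cache$enc, model, "train")
    grads <- enc_g
    grads$attn <- list(W = ab$dW, b = ab$db, u = ab$du)
  } else if (model$variant == "backbone") {
    dsteps <- unstack_steps(dfeat, cfg$per_step_width, cache$enc$T_)
    grads <- encoder_bwd(dsteps, cache$enc, model, "train")
  } else {
    ab <- attention_bwd(dfeat, cache$attn, p$attn)
    T_ <- cache$enc$T_
    n <- cache$n
    dsteps <- lapply(seq_len(T_), function(t) {
      ab$dFeat[, (0:(n - 1L)) * T_ + t, drop = FALSE]
    })
    grads <- encoder_bwd(dsteps, cache$enc, model, "train")
    grads$attn <- list(W = ab$dW, b = ab$db, u = ab$du)
  }
  grads$clf1 <- list(W = lb1$dW, b = lb1$db)
  grads$clf2 <- list(W = lb2$dW, b = lb2$db)
  # order grads to mirror the params tree exactly
  grads[names(model$params)]
}

# ---- losses --------------------------------------------------------------

#' Binary cross-entropy loss for multilabel predictions
#'
#' `-sum_k [y_k log z_k + (1 - y_k) log(1 - z_k)]`, summed over classes and
#' averaged over the batch, with probabilities clipped to
#' `[eps, 1 - eps]`.
#'
#' @param pred `n x C` matrix of probabilities.
#' @param labels `n x C` matrix with entries in `{0, 1}`.
#' @param eps Clipping constant.
#' @return Scalar loss.
#' @export
bce_loss <- function(pred, labels, eps = 1e-7) {
  pred <- as.matrix(pred)
  labels <- as.matrix(labels)
  if (!all(dim(pred) == dim(labels))) stopf("pred/labels dimension mismatch")
  if (!all(labels %in% c(0, 1))) stopf("labels must be 0/1")
  z <- pmin(pmax(pred, eps), 1 - eps)
  -mean(rowSums(labels * log(z) + (1 - labels) * log(1 - z)))
}

#' L2 penalty over model weights
#'
#' Sum of squares of all weight-matrix entries (Eq.-(10)-style
#' `sum(theta^2)`), excluding biases and batch-norm scale/shift.  Composed
#' into the training loss as `loss + l2_weight * l2_penalty(params)`.
#'
#' @param params Nested parameter list (from an `ecg_model`), or a plain
#'   numeric vector (sum of squares of all entries).
#' @return Scalar penalty.
#' @export
l2_penalty <- function(params) {
  if (is.numeric(params)) return(sum(params^2))
  walk <- function(x, nm) {
    if (is.list(x)) {
      return(sum(vapply(seq_along(x), function(i) {
        walk(x[[i]], if (is.null(names(x))) "" else names(x)[i])
      }, numeric(1))))
    }
    if (is_weight_name(nm)) sum(x^2) else 0
  }
  walk(params, "")
}

is_weight_name <- function(nm) grepl("^[WU]", nm) || identical(nm, "u")

# Add the gradient of lambda * l2_penalty to a gradient tree (in place
# semantics via return value).
add_l2_grads <- function(grads, params, lambda) {
  walk <- function(g, p, nm) {
    if (is.list(g)) {
      for (i in seq_along(g)) {
        g[[i]] <- walk(g[[i]], p[[i]],
                       if (is.null(names(g))) "" else names(g)[i])
      }
      return(g)
    }
    if (is_weight_name(nm)) g + 2 * lambda * p else g
  }
  walk(grads, params, "")
}

# Loss + gradients for one batch.  labels: n x n_classes.
model_loss_grads <- function(model, input, labels, mode = "train") {
  fw <- model_forward(model, input, mode)
  n <- nrow(fw$probs)
  y <- t(labels)                      # n_classes x n
  z <- fw$cache$probs_t
  loss_bce <- bce_loss(fw$probs, labels)
  dlogits <- (z - y) / n
  grads <- model_backward(model, fw$cache, dlogits)
  lambda <- model$cfg$l2_weight
  loss <- loss_bce
  if (lambda > 0) {
    loss <- loss + lambda * l2_penalty(model$params)
    grads <- add_l2_grads(grads, model$params, lambda)
  }
  list(loss = loss, loss_bce = loss_bce, grads = grads, probs = fw$probs,
       buffers = fw$buffers)
}

# ---- spec-level encoder views -------------------------------------------

#' Encode beats with the convolutional stack only
#'
#' Applies the shared six-layer convolution encoder (weights identical for
#' every beat slot) to each beat of a beat set.
#'
#' @param beats A `beat_set` from [segment_record()], or an `S x D x L_b`
#'   array.
#' @param model An `ecg_model`.
#' @param mode `"eval"` or `"train"`.
#' @return `S x C_last x T` array of per-beat feature maps.
#' @export
encode_beat_cnn <- function(beats, model, mode = "eval") {
  arr <- if (inherits(beats, "beat_set")) beats$beats else beats
  S <- dim(arr)[1]
  cfg <- model$cfg
  if (dim(arr)[2] != cfg$D || dim(arr)[3] != cfg$L_b) {
    stopf("beats are %d x %d (leads x samples) but the model expects %d x %d",
          dim(arr)[2], dim(arr)[3], cfg$D, cfg$L_b)
  }
  X <- matrix(aperm(arr, c(2, 3, 1)), nrow = cfg$D)
  p <- model$params
  buf <- model$buffers
  cur <- X
  Lc <- cfg$L_b
  for (l in seq_along(cfg$conv_channels)) {
    cv <- conv1d_fwd(cur, p$conv[[l]]$W, p$conv[[l]]$b, Lc, S,
                     cfg$conv_strides[l], cfg$kernel_size)
    Lc <- Lc %/% cfg$conv_strides[l]
    bnr <- bn_fwd(cv$out, p$bn[[l]]$gamma, p$bn[[l]]$beta,
                  buf[[l]]$mean, buf[[l]]$var, mode)
    rl <- relu_fwd(bnr$out)
    cur <- if (l %% 2 == 0) dropout_fwd(rl$out, cfg$dropout_rate, mode)$out
           else rl$out
  }
  C_last <- cfg$conv_channels[length(cfg$conv_channels)]
  aperm(array(cur, dim = c(C_last, Lc, S)), c(3, 1, 2))
}

#' Encode feature maps with the recurrent head
#'
#' Runs the bidirectional GRU over the time steps of per-beat feature maps,
#' concatenates the two directions, applies the shared per-step linear
#' layer, and flattens to one feature vector per beat.
#'
#' @param feature_maps `S x C x T` array (from [encode_beat_cnn()]).
#' @param model An `ecg_model`.
#' @return `S x beat_feature_dim` matrix of per-beat features.
#' @export
encode_beat_rnn <- function(feature_maps, model) {
  S <- dim(feature_maps)[1]
  T_ <- dim(feature_maps)[3]
  p <- model$params
  Xsteps <- lapply(seq_len(T_), function(t) t(feature_maps[, , t]))
  if (S == 1) Xsteps <- lapply(Xsteps, function(x) matrix(x, ncol = 1))
  gf <- gru_dir_fwd(Xsteps, p$gru$fwd)
  gb <- gru_dir_fwd(rev(Xsteps), p$gru$bwd)
  w <- model$cfg$per_step_width
  F_ <- matrix(0, w * T_, S)
  for (t in seq_len(T_)) {
    Hc <- rbind(gf$H[[t]], gb$H[[T_ + 1L - t]])
    F_[(t - 1L) * w + seq_len(w), ] <- p$step_lin$W %*% Hc + p$step_lin$b
  }
  t(F_)
}

#' Fuse per-beat features with masked attention
#'
#' Projects each feature vector with `tanh(W f + b)`, scores it against the
#' context vector `u`, applies a masked softmax (padded slots get zero
#' weight), and returns the weighted average.
#'
#' @param features `S x n_feat` matrix of per-beat features.
#' @param mask Length-`S` 0/1 validity vector.
#' @param params Attention parameters (list with `W`, `b`, `u`), e.g.
#'   `model$params$attn`.
#' @return List with `alpha` (length-`S` weights; zero on masked slots,
#'   summing to one over valid slots) and `f_att` (fused feature vector).
#' @export
attention_fuse <- function(features, mask, params) {
  if (sum(mask) == 0) stopf("attention requires at least one valid beat")
  S <- nrow(features)
  at <- attention_fwd(t(features), as.numeric(mask), S, 1L, params)
  list(alpha = as.numeric(at$alpha), f_att = as.numeric(at$f_att))
}

#' Build the record array for unsegmented variants
#'
#' @param records List of `ecg_record` objects of equal length.
#' @return `n x D x L` array.
#' @export
record_array <- function(records) {
  n <- length(records)
  d <- ncol(records[[1]]$signal)
  L <- nrow(records[[1]]$signal)
  arr <- array(0, dim = c(n, d, L))
  for (i in seq_len(n)) arr[i, , ] <- t(records[[i]]$signal)
  arr
}
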