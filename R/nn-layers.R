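# Neural-network layer primitives: forward passes with caches, and the
# matching analytic backward passes.  Everything operates on matrices whose
# columns are (time position x sequence) pairs, so one BLAS matrix product
# serves a whole batch of beats.
#
# Layouts
#   - A batch of nb sequences of length L with C channels is a C x (L*nb)
#     matrix; column (b-1)*L + t holds channel values of sequence b at t.
#   - Convolution weights are C_out x (k*C_in), columns grouped by kernel
#     offset (im2col layout); bias length C_out.

# ---- 1-D convolution (stride, symmetric zero padding, odd kernel) --------

conv1d_fwd <- function(X, W, b, L, nb, stride, k) {
  C <- nrow(X)
  if (L %% stride != 0) stopf("sequence length %d not divisible by stride %d", L, stride)
  pad <- (k - 1L) %/% 2L
  Lp <- L + 2L * pad
  L_out <- L %/% stride

  inner <- rep((0:(nb - 1L)) * Lp, each = L) + rep((pad + 1L):(pad + L), nb)
  Xp <- matrix(0, C, Lp * nb)
  Xp[, inner] <- X

  base <- rep((0:(nb - 1L)) * Lp, each = L_out) +
    rep(seq(1L, by = stride, length.out = L_out), nb)
  Xcol <- matrix(0, k * C, L_out * nb)
  for (o in seq_len(k)) {
    Xcol[((o - 1L) * C + 1L):(o * C), ] <- Xp[, base + (o - 1L)]
  }
  out <- W %*% Xcol + b
  list(out = out,
       cache = list(Xcol = Xcol, base = base, inner = inner, C = C,
                    Lp = Lp, nb = nb, L_out = L_out, k = k))
}

conv1d_bwd <- function(dY, W, cache) {
  ca <- cache
  dW <- dY %*% t(ca$Xcol)
  db <- rowSums(dY)
  dXcol <- crossprod(W, dY)
  dXp <- matrix(0, ca$C, ca$Lp * ca$nb)
  for (o in seq_len(ca$k)) {
    cols <- ca$base + (o - 1L)
    dXp[, cols] <- dXp[, cols] + dXcol[((o - 1L) * ca$C + 1L):(o * ca$C), ]
  }
  list(dX = dXp[, ca$inner], dW = dW, db = db)
}

# ---- batch normalization (per channel = per row) -------------------------

bn_fwd <- function(X, gamma, beta, rmean, rvar, mode, momentum = 0.1,
                   eps = 1e-5) {
  if (mode == "train") {
    mu <- rowMeans(X)
    xc <- X - mu
    v <- rowMeans(xc * xc)   # biased (1/N) variance
    istd <- 1 / sqrt(v + eps)
    xhat <- xc * istd
    rmean <- (1 - momentum) * rmean + momentum * mu
    rvar <- (1 - momentum) * rvar + momentum * v
  } else {
    istd <- 1 / sqrt(rvar + eps)
    xhat <- (X - rmean) * istd
  }
  list(out = gamma * xhat + beta,
       cache = list(xhat = xhat, istd = istd, mode = mode),
       rmean = rmean, rvar = rvar)
}

bn_bwd <- function(dY, gamma, cache) {
  xhat <- cache$xhat
  dgamma <- rowSums(dY * xhat)
  dbeta <- rowSums(dY)
  if (cache$mode == "train") {
    N <- ncol(dY)
    dX <- (gamma * cache$istd) * (dY - dbeta / N - xhat * (dgamma / N))
  } else {
    dX <- (gamma * cache$istd) * dY
  }
  list(dX = dX, dgamma = dgamma, dbeta = dbeta)
}

# ---- elementwise ---------------------------------------------------------

relu_fwd <- function(X) list(out = pmax(X, 0), cache = X > 0)
relu_bwd <- function(dY, cache) dY * cache

dropout_fwd <- function(X, rate, mode) {
  if (mode != "train" || rate <= 0) {
    return(list(out = X, cache = NULL))
  }
  mask <- (stats::runif(length(X)) >= rate) / (1 - rate)
  dim(mask) <- dim(X)
  list(out = X * mask, cache = mask)
}
dropout_bwd <- function(dY, cache) if (is.null(cache)) dY else dY * cache

linear_fwd <- function(X, W, b) list(out = W %*% X + b, cache = X)
linear_bwd <- function(dY, W, cache) {
  list(dX = crossprod(W, dY), dW = dY %*% t(cache), db = rowSums(dY))
}

# ---- GRU (one direction) -------------------------------------------------
# Gates: update z_t = sigmoid(Wz x_t + Uz h_{t-1} + bz)
#        reset  r_t = sigmoid(Wr x_t + Ur h_{t-1} + br)
#        cand   hc_t = tanh(Wh x_t + Uh (r_t * h_{t-1}) + bh)
#        state  h_t = (1 - z_t) h_{t-1} + z_t hc_t
# Xsteps: list of T matrices (C x nb).  Returns H: list of T (g x nb).

gru_dir_fwd <- function(Xsteps, p) {
  T_ <- length(Xsteps)
  nb <- ncol(Xsteps[[1]])
  g <- length(p$bz)
  h <- matrix(0, g, nb)
  H <- vector("list", T_)
  steps <- vector("list", T_)
  for (t in seq_len(T_)) {
    x <- Xsteps[[t]]
    z <- sigmoid(p$Wz %*% x + p$Uz %*% h + p$bz)
    r <- sigmoid(p$Wr %*% x + p$Ur %*% h + p$br)
    rh <- r * h
    hc <- tanh(p$Wh %*% x + p$Uh %*% rh + p$bh)
    hnew <- (1 - z) * h + z * hc
    steps[[t]] <- list(x = x, hprev = h, z = z, r = r, rh = rh, hc = hc)
    H[[t]] <- hnew
    h <- hnew
  }
  list(H = H, cache = steps)
}

gru_dir_bwd <- function(dH, cache, p) {
  T_ <- length(cache)
  zero_like <- function(a) array(0, dim = dim(a))
  g <- list(Wz = zero_like(p$Wz), Uz = zero_like(p$Uz), bz = 0 * p$bz,
            Wr = zero_like(p$Wr), Ur = zero_like(p$Ur), br = 0 * p$br,
            Wh = zero_like(p$Wh), Uh = zero_like(p$Uh), bh = 0 * p$bh)
  dX <- vector("list", T_)
  dh <- 0
  for (t in rev(seq_len(T_))) {
    s <- cache[[t]]
    dht <- dH[[t]] + dh
    dz <- dht * (s$hc - s$hprev)
    daz <- dz * s$z * (1 - s$z)
    dhc <- dht * s$z
    dah <- dhc * (1 - s$hc^2)
    drh <- crossprod(p$Uh, dah)
    dar <- (drh * s$hprev) * s$r * (1 - s$r)
    dh <- dht * (1 - s$z) + crossprod(p$Uz, daz) + crossprod(p$Ur, dar) +
      drh * s$r
    g$Wz <- g$Wz + daz %*% t(s$x); g$Uz <- g$Uz + daz %*% t(s$hprev)
    g$bz <- g$bz + rowSums(daz)
    g$Wr <- g$Wr + dar %*% t(s$x); g$Ur <- g$Ur + dar %*% t(s$hprev)
    g$br <- g$br + rowSums(dar)
    g$Wh <- g$Wh + dah %*% t(s$x); g$Uh <- g$Uh + dah %*% t(s$rh)
    g$bh <- g$bh + rowSums(dah)
    dX[[t]] <- crossprod(p$Wz, daz) + crossprod(p$Wr, dar) +
      crossprod(p$Wh, dah)
  }
  list(grads = g, dX = dX)
}

#' One GRU cell step
#'
#' Applies the update gate, reset gate, candidate activation and convex
#' state combination of a gated recurrent unit to a single input/state pair.
#' Exposed for verification against independent implementations.
#'
#' @param x_t Input vector (or matrix with one column per batch element).
#' @param h_prev Previous hidden state, same batch layout.
#' @param params List with `Wz, Uz, bz, Wr, Ur, br, Wh, Uh, bh`.
#' @return The new hidden state.
#' @export
gru_cell_step <- function(x_t, h_prev, params) {
  x_t <- as.matrix(x_t)
  h_prev <- as.matrix(h_prev)
  if (!all(is.finite(x_t)) || !all(is.finite(h_prev))) {
    stopf("non-finite inputs to GRU cell")
  }
  p <- params
  z <- sigmoid(p$Wz %*% x_t + p$Uz %*% h_prev + p$bz)
  r <- sigmoid(p$Wr %*% x_t + p$Ur %*% h_prev + p$br)
  hc <- tanh(p$Wh %*% x_t + p$Uh %*% (r * h_prev) + p$bh)
  (1 - z) * h_prev + z * hc
}

# ---- masked attention over slots ----------------------------------------
# Feat: n_feat x (S*n) with slot-major columns per record; maskvec in {0,1}.

attention_fwd <- function(Feat, maskvec, S, n, p) {
  U <- tanh(p$W %*% Feat + p$b)
  sc <- colSums(U * p$u)
  scm <- matrix(sc, S, n)
  mk <- matrix(maskvec, S, n)
  if (any(colSums(mk) == 0)) {
    stopf("attention requires at least one valid slot per record")
  }
  scm[mk == 0] <- -Inf
  mx <- apply(scm, 2, max)
  e <- exp(sweep(scm, 2, mx))
  alpha <- sweep(e, 2, colSums(e), "/")
  n_feat <- nrow(Feat)
  f_att <- matrix(0, n_feat, n)
  for (j in seq_len(n)) {
    cols <- ((j - 1L) * S + 1L):(j * S)
    f_att[, j] <- Feat[, cols, drop = FALSE] %*% alpha[, j]
  }
  list(f_att = f_att, alpha = alpha,
       cache = list(U = U, alpha = alpha, Feat = Feat, S = S, n = n))
}

attention_bwd <- function(df_att, cache, p) {
  S <- cache$S; n <- cache$n
  Feat <- cache$Feat; alpha <- cache$alpha; U <- cache$U
  dalpha <- matrix(0, S, n)
  dFeat <- matrix(0, nrow(Feat), ncol(Feat))
  for (j in seq_len(n)) {
    cols <- ((j - 1L) * S + 1L):(j * S)
    dalpha[, j] <- crossprod(Feat[, cols, drop = FALSE], df_att[, j])
    dFeat[, cols] <- df_att[, j] %*% t(alpha[, j])
  }
  ds <- alpha * sweep(dalpha, 2, colSums(dalpha * alpha))
  dsv <- as.numeric(ds)
  dU <- matrix(p$u, ncol = 1) %*% matrix(dsv, nrow = 1)  # dscore/dU_col = ds * u
  du <- as.numeric(U %*% dsv)
  dpre <- dU * (1 - U^2)
  list(dFeat = dFeat + crossprod(p$W, dpre),
       dW = dpre %*% t(Feat), db = rowSums(dpre), du = du)
}

# ---- nested parameter-list utilities ------------------------------------

# Apply f elementwise across one or more parameter trees of identical shape.
tree_map <- function(f, a, ...) {
  if (is.list(a)) {
    rest <- list(...)
    out <- vector("list", length(a))
    names(out) <- names(a)
    for (i in seq_along(a)) {
      out[[i]] <- do.call(tree_map, c(list(f, a[[i]]), lapply(rest, `[[`, i)))
    }
    out
  } else {
    f(a, ...)
  }
}

tree_sum <- function(a, f = identity) {
  if (is.list(a)) sum(vapply(a, tree_sum, numeric(1), f = f)) else sum(f(a))
}

flatten_params <- function(p) {
  if (is.list(p)) unlist(lapply(p, flatten_params), use.names = FALSE)
  else as.numeric(p)
}

unflatten_params <- function(template, v) {
  pos <- 0L
  fill <- function(x) {
    if (is.list(x)) return(lapply(x, fill))
    n <- length(x)
    out <- v[(pos + 1L):(pos + n)]
    pos <<- pos + n
    dim(out) <- dim(x)
    out
  }
  fill(template)
}
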