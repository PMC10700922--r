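# Independent oracles, coded separately from the package's vectorized paths.

# Brute-force AUC: fraction of concordant positive/negative pairs, ties 1/2.
auc_bruteforce <- function(scores, truth) {
  pos <- scores[truth == 1]
  neg <- scores[truth == 0]
  total <- 0
  for (p in pos) {
    for (q in neg) {
      total <- total + if (p > q) 1 else if (p == q) 0.5 else 0
    }
  }
  total / (length(pos) * length(neg))
}

# Scalar, loop-based GRU cell: update gate, reset gate, candidate, convex
# combination, evaluated element by element.
gru_cell_scalar <- function(x, h_prev, p) {
  g <- length(h_prev)
  sig <- function(v) 1 / (1 + exp(-v))
  h_new <- numeric(g)
  for (i in seq_len(g)) {
    az <- p$bz[i]
    ar <- p$br[i]
    for (j in seq_along(x)) {
      az <- az + p$Wz[i, j] * x[j]
      ar <- ar + p$Wr[i, j] * x[j]
    }
    for (j in seq_len(g)) {
      az <- az + p$Uz[i, j] * h_prev[j]
      ar <- ar + p$Ur[i, j] * h_prev[j]
    }
    z <- sig(az)
    r_i <- sig(ar)
    # note: reset gate for unit j multiplies h_prev[j] inside the candidate
    ah <- p$bh[i]
    for (j in seq_along(x)) ah <- ah + p$Wh[i, j] * x[j]
    for (j in seq_len(g)) {
      rj <- sig({
        tmp <- p$br[j]
        for (k in seq_along(x)) tmp <- tmp + p$Wr[j, k] * x[k]
        for (k in seq_len(g)) tmp <- tmp + p$Ur[j, k] * h_prev[k]
        tmp
      })
      ah <- ah + p$Uh[i, j] * (rj * h_prev[j])
    }
    hc <- tanh(ah)
    h_new[i] <- (1 - z) * h_prev[i] + z * hc
  }
  h_new
}

random_gru_params <- function(input_w, g) {
  list(Wz = matrix(rnorm(g * input_w), g), Uz = matrix(rnorm(g * g), g),
       bz = rnorm(g),
       Wr = matrix(rnorm(g * input_w), g), Ur = matrix(rnorm(g * g), g),
       br = rnorm(g),
       Wh = matrix(rnorm(g * input_w), g), Uh = matrix(rnorm(g * g), g),
       bh = rnorm(g))
}
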