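#!/usr/bin/env Rscript
# Resolve the two free widths of the reference architecture (attention
# dimension A, classifier hidden width h) against the published trainable-
# parameter budget of 569373.
#
# Fixed by the architecture description: 12-lead input, 80-sample beats,
# six conv layers (64,64,128,128,256,256 channels, kernel 3) each followed
# by batch norm, a bidirectional GRU (one bias vector per gate) with a
# shared per-step linear map to 64 features over 10 steps (640 features per
# beat), attention parameters (W: 640 x A, b: A, u: A), and a two-layer
# classifier 640 -> h -> n_c with biases.  Free: A, h, the head size n_c
# (candidates: the six annotation-level class counts), and the GRU hidden
# width g (per direction).
#
# Usage: Rscript scripts/resolve_budget.R

target <- 569373L
conv_ch <- c(64L, 64L, 128L, 128L, 256L, 256L)
conv_in <- c(12L, conv_ch[-6])
kernel <- 3L
conv_par <- sum(conv_in * conv_ch * kernel + conv_ch)  # weights + biases
bn_par <- sum(2L * conv_ch)                            # scale + shift

solutions <- list()
for (g in c(32L, 48L, 64L, 96L, 128L)) {
  gru_par <- 2L * 3L * (256L * g + g * g + g)          # bidirectional
  lin_par <- (2L * g) * 64L + 64L                      # per-step linear
  base <- conv_par + bn_par + gru_par + lin_par
  rem <- target - base
  if (rem <= 0) next
  for (n_c in c(5L, 12L, 19L, 23L, 44L, 71L)) {
    for (h in 1:256) {
      num <- rem - (641L * h + h * n_c + n_c)          # classifier
      if (num <= 0) break
      if (num %% 642L == 0L) {                         # attention: 642 * A
        solutions[[length(solutions) + 1L]] <-
          data.frame(gru_hidden = g, n_classes = n_c, clf_hidden = h,
                     attn_dim = num %/% 642L)
      }
    }
  }
}
solutions <- do.call(rbind, solutions)
solutions <- solutions[order(abs(solutions$gru_hidden - 64),
                             solutions$clf_hidden), ]
cat("Exact solutions for a", target, "parameter budget:\n")
print(solutions, row.names = FALSE)

chosen <- solutions[solutions$gru_hidden == 64, ][1, ]
cat("\nAdopted reference configuration (GRU width 64, smallest classifier):\n")
print(chosen, row.names = FALSE)

# verify against the package if it is installed
if (requireNamespace("beatfuse", quietly = TRUE)) {
  cfg <- beatfuse::model_config(gru_hidden = chosen$gru_hidden,
                                n_classes = chosen$n_classes,
                                clf_hidden = chosen$clf_hidden,
                                attn_dim = chosen$attn_dim)
  m <- beatfuse::build_model("beatfusion", cfg, seed = 1)
  cat(sprintf("\nbeatfuse::count_parameters() check: %d (target %d)\n",
              beatfuse::count_parameters(m), target))
}
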