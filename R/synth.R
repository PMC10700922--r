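# Synthetic 12-lead ECG generator.
#
# Records are built as a superposition of Gaussian wave bumps (P, Q, R, S, T
# plus an ST-segment pedestal), one set per heartbeat, projected onto the 12
# leads by a fixed scaling vector.  Every record carries its true R-peak
# sample indices, so detector and segmentation accuracy can be scored against
# exact ground truth.  Class-conditional morphology changes (ST-segment
# shift, widened QRS, absent P wave) are separable by construction and drive
# the multilabel classification experiments.

# Fixed per-lead projection of the reference waveform (reference lead II = 1).
.lead_scale_12 <- c(
  I = 0.55, II = 1.00, III = 0.45, aVR = -0.75, aVL = 0.30, aVF = 0.65,
  V1 = -0.40, V2 = 0.80, V3 = 1.05, V4 = 1.10, V5 = 0.95, V6 = 0.70
)

#' Registry of synthetic morphology classes
#'
#' @return Character vector of supported class tags. `"NORM"` is the normal
#'   morphology; the remaining tags each perturb one documented wave
#'   parameter: `"ST-shift"` raises the ST-segment pedestal, `"wide-QRS"`
#'   widens the Q/R/S components, `"no-P"` removes the P wave.
#' @export
synth_classes <- function() c("NORM", "ST-shift", "wide-QRS", "no-P")

#' Build a beat morphology template
#'
#' A template is a set of Gaussian wave components (amplitude in mV, centre
#' in seconds relative to the R peak, width = Gaussian sd in seconds) plus a
#' fixed per-lead scaling vector.  A seeded multiplicative jitter (common
#' across class tags for a given seed) is applied to the normal morphology
#' first; class perturbations are then applied exactly, so two templates
#' built with the same seed differ only in the perturbed parameters.
#'
#' @param class_tag Character vector of class tags from [synth_classes()];
#'   several abnormal tags may be combined (co-occurring statements).
#' @param seed Integer seed controlling morphology jitter.
#' @param n_leads Number of leads (12 uses the standard scaling vector; other
#'   values recycle it).
#' @param st_delta ST-segment pedestal amplitude (mV) for `"ST-shift"`.
#' @param qrs_widen Multiplicative width factor for `"wide-QRS"`.
#' @param jitter_sd Relative sd of the seeded amplitude/width jitter.
#' @return An object of class `beat_template`: list with `waves` (data frame
#'   of components), `lead_scale`, `class_tag`, `seed`.
#' @export
make_beat_template <- function(class_tag = "NORM", seed = 1L, n_leads = 12L,
                               st_delta = 0.25, qrs_widen = 1.8,
                               jitter_sd = 0.02) {
  unknown <- setdiff(class_tag, synth_classes())
  if (length(unknown) > 0) {
    stopf("unknown class tag(s) %s; registry: %s",
          paste(sQuote(unknown), collapse = ", "),
          paste(synth_classes(), collapse = ", "))
  }
  waves <- data.frame(
    component = c("P", "Q", "R", "S", "T", "ST"),
    amp    = c(0.15, -0.10, 1.20, -0.25, 0.35, 0.00),
    center = c(-0.20, -0.045, 0.00, 0.045, 0.28, 0.13),
    width  = c(0.025, 0.012, 0.018, 0.014, 0.060, 0.055),
    stringsAsFactors = FALSE
  )
  # seeded jitter, identical for every class tag at a given seed
  jit <- with_seed(seed, stats::rnorm(2 * nrow(waves), 0, jitter_sd))
  waves$amp <- waves$amp * (1 + jit[seq_len(nrow(waves))])
  waves$width <- waves$width * (1 + jit[nrow(waves) + seq_len(nrow(waves))])
  if ("ST-shift" %in% class_tag) waves$amp[waves$component == "ST"] <- st_delta
  if ("wide-QRS" %in% class_tag) {
    qrs <- waves$component %in% c("Q", "R", "S")
    waves$width[qrs] <- waves$width[qrs] * qrs_widen
  }
  if ("no-P" %in% class_tag) waves$amp[waves$component == "P"] <- 0
  lead_scale <- rep_len(.lead_scale_12, n_leads)
  if (n_leads == 12L) names(lead_scale) <- names(.lead_scale_12)
  tpl <- structure(
    list(waves = waves, lead_scale = lead_scale,
         class_tag = class_tag, seed = seed),
    class = "beat_template"
  )
  validate_beat_template(tpl)
  tpl
}

validate_beat_template <- function(tpl) {
  w <- tpl$waves
  if (any(w$width <= 0)) stopf("template widths must be positive")
  core <- w[w$component %in% c("P", "Q", "R", "S", "T"), ]
  ord <- core$center[match(c("P", "Q", "R", "S", "T"), core$component)]
  if (is.unsorted(ord, strictly = TRUE)) {
    stopf("wave centers must be ordered P < Q < R < S < T")
  }
  r_amp <- abs(w$amp[w$component == "R"])
  if (any(abs(core$amp[core$component != "R"]) >= r_amp)) {
    stopf("R amplitude must dominate all other components")
  }
  invisible(tpl)
}

#' Specification for one synthetic ECG record
#'
#' @param fs Sampling rate (Hz).
#' @param duration Record length (s).
#' @param heart_rate Mean heart rate (bpm), within `[30, 220]`.
#' @param rr_jitter Relative RR-interval jitter, in `[0, 0.5)`; jitters are
#'   centred so the beat count stays `floor(duration * heart_rate / 60)`.
#' @param noise_sd Additive white-noise sd (mV); ignored when `snr_db` given.
#' @param snr_db Optional target signal-to-noise ratio (dB) on the reference
#'   lead; overrides `noise_sd`.
#' @param baseline_wander_amp Amplitude (mV) of a 0.33 Hz sinusoidal baseline
#'   wander with a seeded per-lead phase.
#' @param class_label Character vector of class tags; `"NORM"` or one or more
#'   abnormal tags.
#' @param abnormal_beat_indices Beat ordinals (1-based) rendered with the
#'   abnormal template; `NULL` means all beats when the record is abnormal.
#' @param n_leads Number of leads.
#' @param seed Integer seed; fixed seed gives bit-identical records.
#' @return An object of class `synth_spec`.
#' @export
synth_spec <- function(fs = 100, duration = 10, heart_rate = 72,
                       rr_jitter = 0.05, noise_sd = 0.05, snr_db = NULL,
                       baseline_wander_amp = 0.05, class_label = "NORM",
                       abnormal_beat_indices = NULL, n_leads = 12L,
                       seed = 1L) {
  if (fs <= 0 || duration <= 0) stopf("fs and duration must be positive")
  if (heart_rate < 30 || heart_rate > 220) {
    stopf("heart_rate must be in [30, 220] bpm")
  }
  if (rr_jitter < 0 || rr_jitter >= 0.5) stopf("rr_jitter must be in [0, 0.5)")
  if (noise_sd < 0) stopf("noise_sd must be non-negative")
  structure(
    list(fs = fs, duration = duration, heart_rate = heart_rate,
         rr_jitter = rr_jitter, noise_sd = noise_sd, snr_db = snr_db,
         baseline_wander_amp = baseline_wander_amp, class_label = class_label,
         abnormal_beat_indices = abnormal_beat_indices, n_leads = n_leads,
         seed = as.integer(seed)),
    class = "synth_spec"
  )
}

# Evaluate a template's reference waveform contribution at times t (s)
# relative to the R peak.
.template_wave <- function(tpl, t) {
  out <- numeric(length(t))
  w <- tpl$waves
  for (i in seq_len(nrow(w))) {
    if (w$amp[i] == 0) next
    out <- out + w$amp[i] * exp(-((t - w$center[i])^2) / (2 * w$width[i]^2))
  }
  out
}

#' Synthesize one ECG record
#'
#' Generates `floor(duration * heart_rate / 60)` heartbeats at jittered RR
#' intervals, renders each beat from its morphology template on all leads,
#' and adds white noise and baseline wander.  True R-peak sample indices
#' (1-based) are stored alongside the signal.
#'
#' @param spec A [synth_spec()].
#' @return An object of class `ecg_record`: list with `signal` (L x D matrix,
#'   mV), `fs`, `rpeaks_true` (1-based sample indices), `labels` (multi-hot
#'   over [synth_classes()]), `class_label`, `abnormal_beats`, `spec`.
#' @export
synthesize_record <- function(spec) {
  stopifnot(inherits(spec, "synth_spec"))
  n_samp <- round(spec$fs * spec$duration)
  n_beats <- floor(spec$duration * spec$heart_rate / 60)
  if (n_beats < 1) {
    stopf("heart rate %.1f bpm too low: no complete beat fits in %.2f s",
          spec$heart_rate, spec$duration)
  }
  rr <- 60 / spec$heart_rate

  with_seed(spec$seed, {
    jit <- if (spec$rr_jitter > 0) {
      j <- stats::runif(n_beats, -spec$rr_jitter, spec$rr_jitter)
      j - mean(j)
    } else {
      numeric(n_beats)
    }
    rr_i <- rr * (1 + jit)
    t_r <- rr / 2 + cumsum(rr_i) - rr_i[1]
    # guard against jitter pushing the last beat past the record end
    lim <- spec$duration - rr / 4
    if (t_r[n_beats] > lim) t_r <- rr / 2 + (t_r - rr / 2) * (lim - rr / 2) / (t_r[n_beats] - rr / 2)

    abn <- spec$abnormal_beat_indices
    is_abnormal_record <- !identical(spec$class_label, "NORM")
    if (is_abnormal_record && is.null(abn)) abn <- seq_len(n_beats)
    abn <- intersect(as.integer(abn), seq_len(n_beats))

    tpl_norm <- make_beat_template("NORM", seed = spec$seed,
                                   n_leads = spec$n_leads)
    tpl_abn <- if (is_abnormal_record) {
      make_beat_template(spec$class_label, seed = spec$seed,
                         n_leads = spec$n_leads)
    } else {
      tpl_norm
    }

    tt <- (seq_len(n_samp) - 1) / spec$fs
    ref <- numeric(n_samp)
    for (b in seq_len(n_beats)) {
      tpl <- if (b %in% abn) tpl_abn else tpl_norm
      ref <- ref + .template_wave(tpl, tt - t_r[b])
    }
    sig <- outer(ref, tpl_norm$lead_scale)

    if (!is.null(spec$snr_db)) {
      noise_sd <- sqrt(mean(ref^2)) / 10^(spec$snr_db / 20)
    } else {
      noise_sd <- spec$noise_sd
    }
    if (noise_sd > 0) {
      sig <- sig + matrix(stats::rnorm(length(sig), 0, noise_sd),
                          nrow = n_samp)
    }
    if (spec$baseline_wander_amp > 0) {
      phase <- stats::runif(spec$n_leads, 0, 2 * pi)
      bw <- spec$baseline_wander_amp *
        sin(outer(2 * pi * 0.33 * tt, rep(1, spec$n_leads)) +
              matrix(phase, n_samp, spec$n_leads, byrow = TRUE))
      sig <- sig + bw
    }

    rpeaks <- pmin(pmax(round(t_r * spec$fs) + 1L, 1L), n_samp)
    labels <- stats::setNames(integer(length(synth_classes())),
                              synth_classes())
    labels[spec$class_label] <- 1L

    rec <- structure(
      list(signal = sig, fs = spec$fs, rpeaks_true = as.integer(rpeaks),
           labels = labels, class_label = spec$class_label,
           abnormal_beats = abn, spec = spec),
      class = "ecg_record"
    )
    validate_ecg_record(rec)
    rec
  })
}

validate_ecg_record <- function(rec) {
  if (!all(is.finite(rec$signal))) stopf("signal contains non-finite values")
  p <- rec$rpeaks_true
  if (!is.null(p)) {
    if (is.unsorted(p, strictly = TRUE)) {
      stopf("rpeaks_true must be strictly increasing")
    }
    if (any(p < 1) || any(p > nrow(rec$signal))) {
      stopf("rpeaks_true out of record range")
    }
  }
  if (!is.null(rec$labels) && !all(rec$labels %in% c(0L, 1L))) {
    stopf("labels must be 0/1")
  }
  invisible(rec)
}

#' @export
print.ecg_record <- function(x, ...) {
  cat(sprintf("<ecg_record> %d samples x %d leads @ %g Hz, %d beats, class: %s\n",
              nrow(x$signal), ncol(x$signal), x$fs,
              length(x$rpeaks_true), paste(x$class_label, collapse = "+")))
  invisible(x)
}

#' Synthesize a labelled dataset of ECG records
#'
#' Class counts follow `class_mix` by largest-remainder apportionment (every
#' count within one of `n_records * proportion`), record order is shuffled,
#' and each record gets its own seed derived from the master seed.
#'
#' @param n_records Number of records.
#' @param class_mix Named proportions over class tags; names may combine
#'   abnormal tags with `"+"` (e.g. `"ST-shift+no-P"`) for co-occurring
#'   labels. Must sum to 1.
#' @param spec_defaults A [synth_spec()] providing everything except class
#'   label and seed.
#' @param seed Master seed.
#' @param abnormal_frac Fraction of beats carrying the abnormal morphology in
#'   abnormal records (1 = every beat). The affected beat ordinals are drawn
#'   per record.
#' @return List of [ecg_record][synthesize_record] objects, with attributes
#'   `class_names` (label columns) and `label_matrix` (n x C multi-hot).
#' @export
synthesize_dataset <- function(n_records, class_mix,
                               spec_defaults = synth_spec(), seed = 1L,
                               abnormal_frac = 1) {
  if (!is_count(n_records)) stopf("n_records must be a positive integer")
  if (abs(sum(class_mix) - 1) > 1e-8) stopf("class_mix must sum to 1")
  if (is.null(names(class_mix))) stopf("class_mix must be named")

  # largest-remainder apportionment
  quota <- n_records * class_mix
  counts <- floor(quota)
  rem <- n_records - sum(counts)
  if (rem > 0) {
    extra <- order(quota - counts, decreasing = TRUE)[seq_len(rem)]
    counts[extra] <- counts[extra] + 1
  }
  assignment <- rep(names(class_mix), counts)
  seeds <- derive_seeds(seed, n_records + 1L)
  assignment <- with_seed(seeds[n_records + 1L], sample(assignment))

  records <- vector("list", n_records)
  for (i in seq_len(n_records)) {
    tags <- strsplit(assignment[i], "+", fixed = TRUE)[[1]]
    sp <- spec_defaults
    sp$class_label <- tags
    sp$seed <- seeds[i]
    if (!identical(tags, "NORM") && abnormal_frac < 1) {
      n_beats <- floor(sp$duration * sp$heart_rate / 60)
      k <- max(1L, round(abnormal_frac * n_beats))
      sp$abnormal_beat_indices <- with_seed(seeds[i] + 1L,
                                            sort(sample.int(n_beats, k)))
    }
    records[[i]] <- synthesize_record(sp)
  }
  cls <- synth_classes()
  lab <- t(vapply(records, function(r) r$labels[cls], numeric(length(cls))))
  colnames(lab) <- cls
  attr(records, "class_names") <- cls
  attr(records, "label_matrix") <- lab
  records
}
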