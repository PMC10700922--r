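# Pan-Tompkins R-peak detection, adapted to 100 Hz sampling.
#
# The classic five-stage pipeline: bandpass filter, differentiator, squaring,
# moving-window integration, adaptive thresholding.  The original integer
# filters were designed for 200 Hz; here the bandpass is a second-order
# zero-phase Butterworth (5-15 Hz) and the derivative the standard five-point
# kernel, so the detector works at arbitrary sampling rates.  All thresholds
# adapt to the signal, making detection invariant to amplitude scaling.

#' Detector configuration
#'
#' @param band_low,band_high Bandpass edges (Hz); must satisfy
#'   `0 < band_low < band_high < fs/2` at use time.
#' @param integration_window Moving-window integration length (s); the
#'   canonical 150 ms covers one QRS complex.
#' @param refractory Minimum spacing between detections (s); 200 ms is the
#'   physiological lower bound on QRS separation.
#' @param detection_lead Lead (column) the detector runs on; default 2
#'   (lead II, the clinical rhythm lead).
#' @param threshold_init_fraction Fraction of the peak transformed amplitude
#'   in the learning phase (first 2 s) used to initialize the signal level.
#' @param refine_window Half-width (s) of the window used to snap each
#'   detection to the local maximum of the raw detection lead.
#' @return An object of class `detector_config`.
#' @export
detector_config <- function(band_low = 5, band_high = 15,
                            integration_window = 0.150, refractory = 0.200,
                            detection_lead = 2L,
                            threshold_init_fraction = 0.25,
                            refine_window = 0.100) {
  if (band_low <= 0 || band_high <= band_low) {
    stopf("need 0 < band_low < band_high")
  }
  if (integration_window <= 0 || refractory <= 0) {
    stopf("integration_window and refractory must be positive")
  }
  structure(
    list(band_low = band_low, band_high = band_high,
         integration_window = integration_window, refractory = refractory,
         detection_lead = as.integer(detection_lead),
         threshold_init_fraction = threshold_init_fraction,
         refine_window = refine_window),
    class = "detector_config"
  )
}

#' Pan-Tompkins feature transform
#'
#' Applies the first four stages: zero-phase 5-15 Hz bandpass, five-point
#' derivative, squaring, and a centred moving-window integration.  The output
#' is a non-negative envelope of QRS energy, the input to thresholding.
#'
#' @param signal_1lead Numeric vector, one lead.
#' @param fs Sampling rate (Hz).
#' @param cfg A [detector_config()].
#' @return Non-negative numeric vector, same length as the input.
#' @export
pt_transform <- function(signal_1lead, fs, cfg = detector_config()) {
  if (cfg$band_high >= fs / 2) {
    stopf("band_high (%g Hz) must be below the Nyquist frequency (%g Hz)",
          cfg$band_high, fs / 2)
  }
  n <- length(signal_1lead)
  w <- max(1L, round(cfg$integration_window * fs))
  if (n < w) stopf("signal shorter than the integration window")

  bp <- signal::butter(2, c(cfg$band_low, cfg$band_high) / (fs / 2),
                       type = "pass")
  filtered <- as.numeric(signal::filtfilt(bp, signal_1lead))

  # five-point derivative: (2x[n+1] + x[n+2] - x[n-2] - 2x[n-1]) / 8
  d <- numeric(n)
  idx <- 3:(n - 2)
  d[idx] <- (2 * filtered[idx + 1] + filtered[idx + 2] -
               filtered[idx - 2] - 2 * filtered[idx - 1]) / 8

  sq <- d^2

  # centred moving-window integration
  cs <- cumsum(c(0, sq))
  half <- w %/% 2
  lo <- pmax(idx_range <- seq_len(n) - half, 1L)
  hi <- pmin(seq_len(n) + (w - half - 1L), n)
  (cs[hi + 1L] - cs[lo]) / w
}

#' Detect R-peaks with adaptive thresholding
#'
#' Runs [pt_transform()] on the detection lead, picks candidate peaks of the
#' integrated envelope, classifies them against adaptive signal/noise levels
#' (Pan-Tompkins running estimates), performs a search-back pass at half
#' threshold whenever an RR interval exceeds 1.66 times the running RR
#' average, and snaps every detection to the local maximum of the raw
#' detection lead within `refine_window`.
#'
#' @param record An `ecg_record` (or any list with `signal` matrix and `fs`).
#' @param cfg A [detector_config()].
#' @return An object of class `rpeak_list`: list with `indices` (1-based,
#'   strictly increasing, spaced by at least the refractory) and `fs`.
#' @export
detect_rpeaks <- function(record, cfg = detector_config()) {
  sig <- record$signal
  fs <- record$fs
  if (is.null(dim(sig))) sig <- matrix(sig, ncol = 1)
  if (cfg$detection_lead > ncol(sig)) {
    stopf("detection_lead %d exceeds the %d available leads",
          cfg$detection_lead, ncol(sig))
  }
  n <- nrow(sig)
  if (n < 2 * fs) stopf("record shorter than 2 s: too short for threshold adaptation")
  x <- sig[, cfg$detection_lead]

  if (all(x == 0)) {
    return(structure(list(indices = integer(0), fs = fs),
                     class = "rpeak_list"))
  }

  env <- pt_transform(x, fs, cfg)
  refr <- max(1L, round(cfg$refractory * fs))

  # candidate peaks: local maxima of the envelope
  cand <- which(diff(sign(diff(env))) < 0) + 1L
  cand <- cand[env[cand] > 0]
  if (length(cand) == 0) {
    return(structure(list(indices = integer(0), fs = fs),
                     class = "rpeak_list"))
  }

  # learning phase: first 2 s
  learn <- env[seq_len(min(n, round(2 * fs)))]
  spki <- cfg$threshold_init_fraction * max(learn)
  npki <- 0.5 * mean(learn)

  peaks <- integer(0)
  rr_hist <- numeric(0)
  last_qrs <- -Inf

  classify <- function(i, thr) env[i] > thr

  k <- 1L
  while (k <= length(cand)) {
    i <- cand[k]
    thr <- npki + 0.25 * (spki - npki)
    if (i - last_qrs >= refr && classify(i, thr)) {
      if (length(peaks) > 0) rr_hist <- c(rr_hist, i - last_qrs)
      peaks <- c(peaks, i)
      last_qrs <- i
      spki <- 0.125 * env[i] + 0.875 * spki
    } else {
      npki <- 0.125 * env[i] + 0.875 * npki
      # search-back: expected beat missed?
      if (length(rr_hist) >= 2) {
        rr_avg <- mean(utils::tail(rr_hist, 8))
        if (i - last_qrs > 1.66 * rr_avg) {
          gap <- cand[cand > last_qrs + refr & cand < i]
          if (length(gap) > 0) {
            thr2 <- 0.5 * thr
            best <- gap[which.max(env[gap])]
            if (env[best] > thr2) {
              rr_hist <- c(rr_hist, best - last_qrs)
              peaks <- c(peaks, best)
              last_qrs <- best
              spki <- 0.25 * env[best] + 0.75 * spki
              next  # re-examine current candidate against updated state
            }
          }
        }
      }
    }
    k <- k + 1L
  }

  # refine to local maximum of the raw detection lead
  half <- max(1L, round(cfg$refine_window * fs))
  refined <- vapply(peaks, function(p) {
    lo <- max(1L, p - half); hi <- min(n, p + half)
    as.integer(lo + which.max(x[lo:hi]) - 1L)
  }, integer(1))

  # deduplicate and enforce refractory spacing after refinement
  refined <- sort(unique(refined))
  if (length(refined) > 1) {
    keep <- refined[1]
    for (p in refined[-1]) {
      if (p - keep[length(keep)] >= refr) {
        keep <- c(keep, p)
      } else if (x[p] > x[keep[length(keep)]]) {
        keep[length(keep)] <- p
      }
    }
    refined <- keep
  }

  structure(list(indices = as.integer(refined), fs = fs),
            class = "rpeak_list")
}

#' @export
print.rpeak_list <- function(x, ...) {
  cat(sprintf("<rpeak_list> %d peaks @ %g Hz\n", length(x$indices), x$fs))
  invisible(x)
}

#' Score detections against ground truth
#'
#' Matches detected peaks to reference peaks one-to-one by nearest neighbour
#' within a tolerance and reports sensitivity and positive predictive value.
#'
#' @param detected,truth Integer sample indices.
#' @param fs Sampling rate (Hz).
#' @param tol_s Matching tolerance (s).
#' @return List with `tp`, `fn`, `fp`, `sensitivity`, `ppv`.
#' @export
score_detections <- function(detected, truth, fs, tol_s = 0.030) {
  tol <- tol_s * fs
  used <- logical(length(detected))
  tp <- 0L
  for (t in truth) {
    if (length(detected) == 0) break
    d <- abs(detected - t)
    d[used] <- Inf
    j <- which.min(d)
    if (length(j) == 1 && d[j] <= tol) {
      used[j] <- TRUE
      tp <- tp + 1L
    }
  }
  fn <- length(truth) - tp
  fp <- length(detected) - tp
  list(tp = tp, fn = fn, fp = fp,
       sensitivity = if (length(truth)) tp / length(truth) else NA_real_,
       ppv = if (length(detected)) tp / length(detected) else NA_real_)
}
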