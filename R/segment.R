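# Heartbeat segmentation: record + R-peaks -> fixed-size masked beat stack.

#' Segmentation configuration
#'
#' @param L_f Samples kept before the R-peak (default 25).
#' @param L_k Samples kept after the R-peak (default 55); beat length is
#'   `L_b = L_f + L_k` (80 in the reference configuration).
#' @param S_max Number of beat slots (default 20); shorter records are
#'   zero-padded with a validity mask, longer ones keep the earliest beats.
#' @return An object of class `segmentation_config`.
#' @export
segmentation_config <- function(L_f = 25L, L_k = 55L, S_max = 20L) {
  if (L_f < 1 || L_k < 1 || S_max < 1) {
    stopf("L_f, L_k and S_max must be positive")
  }
  structure(
    list(L_f = as.integer(L_f), L_k = as.integer(L_k),
         S_max = as.integer(S_max), L_b = as.integer(L_f + L_k)),
    class = "segmentation_config"
  )
}

#' Segment a record into a masked beat stack
#'
#' Each beat is the half-open window of `L_f` samples before and `L_k`
#' samples after an R-peak, across all leads, so the R-peak sits at offset
#' `L_f + 1` within the beat.  Windows running past either record edge are
#' zero-padded on the missing side (the beat is kept).  The first `S_max`
#' beats are retained in temporal order; missing slots are zero beats with
#' `mask = 0`.
#'
#' @param record An `ecg_record` (or list with `signal` matrix).
#' @param peaks An [rpeak_list][detect_rpeaks] or integer vector of 1-based
#'   peak indices.
#' @param cfg A [segmentation_config()].
#' @return An object of class `beat_set`: list with `beats`
#'   (`S_max x D x L_b` array), `mask` (length-`S_max` 0/1 vector with
#'   `s_valid` leading ones), `s_valid`, `peaks_used`, `empty` (flag set when
#'   no peaks were supplied), `cfg`.
#' @export
segment_record <- function(record, peaks, cfg = segmentation_config()) {
  sig <- record$signal
  if (is.null(dim(sig))) sig <- matrix(sig, ncol = 1)
  if (inherits(peaks, "rpeak_list")) peaks <- peaks$indices
  peaks <- as.integer(peaks)
  n <- nrow(sig)
  d <- ncol(sig)
  L_b <- cfg$L_b

  beats <- array(0, dim = c(cfg$S_max, d, L_b))
  empty <- length(peaks) == 0
  if (empty) {
    warning("no R-peaks supplied: returning an all-masked beat set",
            call. = FALSE)
  }
  if (any(peaks < 1 | peaks > n)) stopf("peak indices outside the record")

  used <- utils::head(peaks, cfg$S_max)
  s_valid <- length(used)
  for (i in seq_along(used)) {
    r <- used[i]
    src <- (r - cfg$L_f):(r + cfg$L_k - 1L)
    ok <- src >= 1L & src <= n
    beats[i, , which(ok)] <- t(sig[src[ok], , drop = FALSE])
  }
  mask <- c(rep(1L, s_valid), rep(0L, cfg$S_max - s_valid))

  structure(
    list(beats = beats, mask = mask, s_valid = s_valid,
         peaks_used = used, empty = empty, cfg = cfg),
    class = "beat_set"
  )
}

#' @export
print.beat_set <- function(x, ...) {
  cat(sprintf("<beat_set> %d/%d valid beats, %d leads x %d samples\n",
              x$s_valid, length(x$mask), dim(x$beats)[2], dim(x$beats)[3]))
  invisible(x)
}

#' Segment a dataset of records for training
#'
#' Runs peak detection (or uses the generator's ground-truth peaks) and
#' segmentation on every record, returning dense arrays ready for the model.
#'
#' @param records List of `ecg_record` objects (e.g. from
#'   [synthesize_dataset()]).
#' @param scfg A [segmentation_config()].
#' @param peaks `"detect"` to run [detect_rpeaks()] (the full pipeline) or
#'   `"true"` to use `rpeaks_true`.
#' @param dcfg A [detector_config()] (used when `peaks = "detect"`).
#' @return List with `beats` (`n x S_max x D x L_b` array), `mask`
#'   (`n x S_max`), `labels` (`n x C` multi-hot, when records carry labels),
#'   `class_names`.
#' @export
prepare_beat_data <- function(records, scfg = segmentation_config(),
                              peaks = c("detect", "true"),
                              dcfg = detector_config()) {
  peaks <- match.arg(peaks)
  n <- length(records)
  d <- ncol(records[[1]]$signal)
  beats <- array(0, dim = c(n, scfg$S_max, d, scfg$L_b))
  mask <- matrix(0L, n, scfg$S_max)
  for (i in seq_len(n)) {
    p <- if (peaks == "true") records[[i]]$rpeaks_true
         else detect_rpeaks(records[[i]], dcfg)
    bs <- segment_record(records[[i]], p, scfg)
    beats[i, , , ] <- bs$beats
    mask[i, ] <- bs$mask
  }
  labels <- attr(records, "label_matrix")
  if (is.null(labels) && !is.null(records[[1]]$labels)) {
    labels <- t(vapply(records, function(r) as.numeric(r$labels),
                       numeric(length(records[[1]]$labels))))
    colnames(labels) <- names(records[[1]]$labels)
  }
  list(beats = beats, mask = mask, labels = labels,
       class_names = colnames(labels))
}
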