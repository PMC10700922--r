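# Minimal WFDB (PhysioNet) I/O for format-16 signal files: enough to write
# synthetic records as .hea/.dat pairs and to read PTB-XL's records100
# files.  Format 16 is little-endian signed 16-bit with samples interleaved
# across signals; amplitudes are (adc - baseline) / gain in the header's
# physical units.

#' Write a record as a WFDB .hea/.dat pair
#'
#' @param record An `ecg_record` (signal in mV).
#' @param prefix Path prefix; `<prefix>.hea` and `<prefix>.dat` are written.
#' @param gain ADC units per mV.
#' @param lead_names Signal descriptions for the header.
#' @return The prefix, invisibly.
#' @export
write_wfdb <- function(record, prefix, gain = 1000,
                       lead_names = colnames(record$signal)) {
  sig <- record$signal
  if (is.null(dim(sig))) sig <- matrix(sig, ncol = 1)
  nsig <- ncol(sig)
  nsamp <- nrow(sig)
  if (is.null(lead_names)) lead_names <- paste0("ch", seq_len(nsig))
  adc <- round(sig * gain)
  if (any(abs(adc) > 32767)) {
    stopf("signal exceeds the 16-bit ADC range at gain %g", gain)
  }
  name <- basename(prefix)
  hea <- c(
    sprintf("%s %d %g %d", name, nsig, record$fs, nsamp),
    sprintf("%s.dat 16 %g(0)/mV 16 0 %d 0 0 %s", name, gain,
            as.integer(adc[1, ]), lead_names)
  )
  writeLines(hea, paste0(prefix, ".hea"))
  con <- file(paste0(prefix, ".dat"), "wb")
  on.exit(close(con))
  writeBin(as.integer(t(adc)), con, size = 2, endian = "little")
  invisible(prefix)
}

#' Read a WFDB format-16 record
#'
#' @param prefix Path prefix of the `.hea`/`.dat` pair (PhysioNet layout,
#'   e.g. `records100/00000/00001_lr`).
#' @return List with `signal` (samples x signals matrix, converted to the
#'   header's physical units via gain and baseline), `fs`, `lead_names`.
#' @export
read_wfdb <- function(prefix) {
  hea_path <- paste0(prefix, ".hea")
  if (!file.exists(hea_path)) {
    stopf("header not found: %s (expected a WFDB .hea/.dat pair)", hea_path)
  }
  lines <- readLines(hea_path, warn = FALSE)
  lines <- lines[!grepl("^#", lines) & nzchar(trimws(lines))]
  top <- strsplit(trimws(lines[1]), "\\s+")[[1]]
  nsig <- as.integer(top[2])
  fs <- if (length(top) >= 3) as.numeric(top[3]) else 250
  nsamp <- if (length(top) >= 4) as.integer(top[4]) else NA_integer_

  gains <- numeric(nsig)
  baselines <- numeric(nsig)
  lead_names <- character(nsig)
  dat_file <- NULL
  for (i in seq_len(nsig)) {
    f <- strsplit(trimws(lines[1 + i]), "\\s+")[[1]]
    dat_file <- f[1]
    fmt <- sub("x.*", "", f[2])
    if (fmt != "16") stopf("unsupported WFDB format '%s' (only 16)", f[2])
    spec <- f[3]
    m <- regmatches(spec, regexec("^([-0-9.eE+]+)(\\(([-0-9]+)\\))?(/(.*))?$",
                                  spec))[[1]]
    gains[i] <- as.numeric(m[2])
    if (gains[i] == 0) gains[i] <- 200  # WFDB default gain
    baselines[i] <- if (nzchar(m[4])) as.numeric(m[4])
                    else if (length(f) >= 5) as.numeric(f[5]) else 0
    lead_names[i] <- if (length(f) >= 9) f[length(f)] else paste0("ch", i)
  }
  dat_path <- file.path(dirname(prefix), dat_file)
  if (!file.exists(dat_path)) stopf("signal file not found: %s", dat_path)
  raw_n <- file.size(dat_path) / 2
  con <- file(dat_path, "rb")
  on.exit(close(con))
  adc <- readBin(con, integer(), n = raw_n, size = 2, endian = "little",
                 signed = TRUE)
  if (is.na(nsamp)) nsamp <- length(adc) %/% nsig
  m <- t(matrix(adc[seq_len(nsig * nsamp)], nrow = nsig))
  sig <- sweep(sweep(m, 2, baselines), 2, gains, "/")
  colnames(sig) <- lead_names
  list(signal = sig, fs = fs, lead_names = lead_names)
}
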