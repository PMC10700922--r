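# Optional PTB-XL loader: metadata, six-level label aggregation, and the
# recommended fold split.  The database itself is never downloaded; point
# `root` at an existing PTB-XL v1.0.1 directory (ptbxl_database.csv,
# scp_statements.csv, records100/...).

.ptbxl_levels <- c("all", "diag", "subdiag", "superdiag", "form", "rhythm")

#' Load PTB-XL metadata
#'
#' @param root Directory containing `ptbxl_database.csv` and
#'   `scp_statements.csv`.
#' @return List with `records` (one row per record, including parsed
#'   `scp_codes` likelihood lists, `strat_fold` and the 100 Hz file path)
#'   and `statements` (the SCP statement dictionary, keyed by code).
#' @export
load_ptbxl_metadata <- function(root) {
  db_path <- file.path(root, "ptbxl_database.csv")
  scp_path <- file.path(root, "scp_statements.csv")
  missing <- c(db_path, scp_path)[!file.exists(c(db_path, scp_path))]
  if (length(missing) > 0) {
    stopf(paste0(
      "missing PTB-XL file(s): %s\nexpected the PhysioNet v1.0.1 layout:\n",
      "  <root>/ptbxl_database.csv\n  <root>/scp_statements.csv\n",
      "  <root>/records100/<folder>/<record>_lr.(hea|dat)"),
      paste(missing, collapse = ", "))
  }
  records <- utils::read.csv(db_path, stringsAsFactors = FALSE)
  statements <- utils::read.csv(scp_path, stringsAsFactors = FALSE,
                                row.names = 1)
  records$scp_parsed <- lapply(records$scp_codes, parse_scp_codes)
  list(records = records, statements = statements)
}

# Parse a python-dict-style statement string, e.g. "{'NORM': 100.0,'SR': 0.0}"
parse_scp_codes <- function(s) {
  s <- gsub("[{}'\"]", "", s)
  if (!nzchar(trimws(s))) return(stats::setNames(numeric(0), character(0)))
  parts <- strsplit(s, ",")[[1]]
  kv <- strsplit(parts, ":")
  stats::setNames(vapply(kv, function(x) as.numeric(trimws(x[2])),
                         numeric(1)),
                  vapply(kv, function(x) trimws(x[1]), character(1)))
}

#' Label scheme for a PTB-XL annotation level
#'
#' @param level One of `"all"`, `"diag"`, `"subdiag"`, `"superdiag"`,
#'   `"form"`, `"rhythm"`.
#' @param statements Statement dictionary from [load_ptbxl_metadata()].
#' @return List with `level`, `class_names`, `n_c`, and `code_map` (named
#'   list mapping each SCP code to the class names it contributes to).
#' @export
label_scheme <- function(level, statements) {
  level <- match.arg(level, .ptbxl_levels)
  st <- statements
  codes <- rownames(st)
  map <- switch(level,
    all = stats::setNames(as.list(codes), codes),
    diag = {
      d <- codes[st$diagnostic %in% 1]
      stats::setNames(as.list(d), d)
    },
    subdiag = {
      d <- codes[st$diagnostic %in% 1 & nzchar(st$diagnostic_subclass)]
      stats::setNames(as.list(st[d, "diagnostic_subclass"]), d)
    },
    superdiag = {
      d <- codes[st$diagnostic %in% 1 & nzchar(st$diagnostic_class)]
      stats::setNames(as.list(st[d, "diagnostic_class"]), d)
    },
    form = {
      d <- codes[st$form %in% 1]
      stats::setNames(as.list(d), d)
    },
    rhythm = {
      d <- codes[st$rhythm %in% 1]
      stats::setNames(as.list(d), d)
    }
  )
  class_names <- sort(unique(unlist(map)))
  list(level = level, class_names = class_names,
       n_c = length(class_names), code_map = map)
}

#' Aggregate record statements into a multi-hot label matrix
#'
#' Maps each record's SCP statements to the scheme's classes.  Statements
#' whose likelihood is below `likelihood_min` are dropped; unknown codes are
#' skipped with a warning.  Records with no class at the chosen level get an
#' all-zero row and are flagged in the `usable` attribute.
#'
#' @param meta Output of [load_ptbxl_metadata()].
#' @param scheme A [label_scheme()].
#' @param likelihood_min Minimum statement likelihood (0 keeps every
#'   assigned statement).
#' @return `n x n_c` 0/1 matrix with attribute `usable` (logical vector).
#' @export
aggregate_labels <- function(meta, scheme, likelihood_min = 0) {
  records <- meta$records
  n <- nrow(records)
  lab <- matrix(0L, n, scheme$n_c,
                dimnames = list(NULL, scheme$class_names))
  known <- names(scheme$code_map)
  all_codes <- rownames(meta$statements)
  unknown_seen <- character(0)
  for (i in seq_len(n)) {
    sc <- records$scp_parsed[[i]]
    sc <- sc[sc >= likelihood_min]
    bad <- setdiff(names(sc), all_codes)
    if (length(bad) > 0) unknown_seen <- union(unknown_seen, bad)
    hits <- unlist(scheme$code_map[intersect(names(sc), known)])
    if (length(hits) > 0) lab[i, unique(hits)] <- 1L
  }
  if (length(unknown_seen) > 0) {
    warning(sprintf("skipped unknown SCP code(s): %s",
                    paste(unknown_seen, collapse = ", ")), call. = FALSE)
  }
  attr(lab, "usable") <- rowSums(lab) > 0
  lab
}

#' Train/test split and cross-validation rotations by stratified fold
#'
#' Fold 10 is the held-out test set; folds 1-9 form the training set,
#' exposed as 9 rotations each holding out one training fold for
#' validation.
#'
#' @param records Record table from [load_ptbxl_metadata()].
#' @return List with `test_idx`, `train_idx`, and `rotations` (list of 9
#'   lists with `train_idx`/`val_idx`).
#' @export
split_folds <- function(records) {
  fold <- records$strat_fold
  if (is.null(fold)) stopf("record table lacks a strat_fold column")
  test_idx <- which(fold == 10)
  train_idx <- which(fold %in% 1:9)
  rotations <- lapply(1:9, function(k) {
    list(train_idx = which(fold %in% setdiff(1:9, k)),
         val_idx = which(fold == k))
  })
  list(test_idx = test_idx, train_idx = train_idx, rotations = rotations)
}

#' Load PTB-XL 100 Hz signals as ECG records
#'
#' @param meta Output of [load_ptbxl_metadata()].
#' @param root PTB-XL root directory.
#' @param idx Row indices of the records to load.
#' @param labels Optional label matrix aligned with `meta$records`.
#' @return List of `ecg_record`-style lists (signal mV, fs, labels).
#' @export
load_ptbxl_signals <- function(meta, root, idx = seq_len(nrow(meta$records)),
                               labels = NULL) {
  lapply(idx, function(i) {
    prefix <- file.path(root, meta$records$filename_lr[i])
    w <- read_wfdb(prefix)
    structure(
      list(signal = w$signal, fs = w$fs, rpeaks_true = NULL,
           labels = if (!is.null(labels)) labels[i, ] else NULL,
           ecg_id = meta$records$ecg_id[i]),
      class = "ecg_record"
    )
  })
}
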