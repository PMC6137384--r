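# Labeled subject-by-feature container and delimited-text I/O.

#' Labeled dataset of subjects by features
#'
#' The ensemble's universe: a numeric subject x feature matrix with class
#' labels +1 (control) / -1 (case) and subject identifiers.
#'
#' @param features Numeric matrix, one row per subject.
#' @param labels Numeric vector of +1 / -1, one per subject.
#' @param subject_ids Character vector of identifiers (default `S1..Sn`).
#' @return An object of class `fc_dataset`.
#' @export
fc_dataset <- function(features, labels, subject_ids = NULL) {
  features <- as.matrix(features)
  if (is.null(subject_ids)) {
    subject_ids <- sprintf("S%d", seq_len(nrow(features)))
  }
  if (!is.numeric(features) || anyNA(features)) {
    stop_invalid("`features` must be a numeric matrix without missing values")
  }
  if (nrow(features) != length(labels)) {
    stop_invalid("%d feature rows but %d labels", nrow(features), length(labels))
  }
  if (!all(labels %in% c(-1, 1))) stop_invalid("labels must be +1 or -1")
  if (length(subject_ids) != nrow(features)) {
    stop_invalid("subject_ids length mismatch")
  }
  structure(list(features = features, labels = as.numeric(labels),
                 subject_ids = as.character(subject_ids)),
            class = "fc_dataset")
}

#' @export
print.fc_dataset <- function(x, ...) {
  cat(sprintf("fc_dataset: %d subjects x %d features (%d labeled +1, %d labeled -1)\n",
              nrow(x$features), ncol(x$features),
              sum(x$labels == 1), sum(x$labels == -1)))
  invisible(x)
}

#' @export
dim.fc_dataset <- function(x) dim(x$features)

# Row subset keeping labels and ids aligned.
subset_rows <- function(D, idx) {
  fc_dataset(D$features[idx, , drop = FALSE], D$labels[idx], D$subject_ids[idx])
}

#' Read one subject's ROI time series from delimited text
#'
#' The file holds a T x R table (rows = timepoints, columns = regions),
#' comma- or tab-separated, with an optional header row of region
#' abbreviations (detected automatically).
#'
#' @param path File path.
#' @param subject_id Identifier for the subject.
#' @param label +1 or -1.
#' @return An [roi_ts()].
#' @export
read_timeseries <- function(path, subject_id, label) {
  first <- readLines(path, n = 1)
  sep <- if (grepl("\t", first)) "\t" else ","
  fields <- strsplit(first, sep, fixed = TRUE)[[1]]
  has_header <- anyNA(suppressWarnings(as.numeric(fields)))
  tab <- read.delim(path, sep = sep, header = has_header)
  roi_ts(subject_id, as.matrix(tab), label)
}

#' Read a cohort from a subject manifest
#'
#' The manifest is a CSV with columns `subject_id`, `path`, `label`
#' (+1/-1). Relative paths are resolved against the manifest's directory.
#'
#' @param manifest_path Path to the manifest CSV.
#' @return List of [roi_ts()] objects in manifest order.
#' @export
read_cohort <- function(manifest_path) {
  man <- read.csv(manifest_path, stringsAsFactors = FALSE)
  need <- c("subject_id", "path", "label")
  if (!all(need %in% names(man))) {
    stop_invalid("manifest must have columns: %s", toString(need))
  }
  base <- dirname(manifest_path)
  lapply(seq_len(nrow(man)), function(r) {
    p <- man$path[r]
    if (!file.exists(p)) p <- file.path(base, man$path[r])
    read_timeseries(p, man$subject_id[r], man$label[r])
  })
}

#' Write a labeled feature matrix to CSV
#'
#' Layout: first column `subject_id`, second `label`, then one column per
#' edge feature (named `FC_i_j` when the feature count matches a region
#' pair universe).
#'
#' @param D An [fc_dataset()].
#' @param path Output CSV path.
#' @export
write_feature_matrix <- function(D, path) {
  stopifnot(inherits(D, "fc_dataset"))
  tab <- data.frame(subject_id = D$subject_ids, label = D$labels,
                    D$features, check.names = FALSE)
  write.csv(tab, path, row.names = FALSE)
  invisible(path)
}

#' Read a labeled feature matrix written by [write_feature_matrix()]
#'
#' @param path CSV path.
#' @return An [fc_dataset()].
#' @export
read_feature_matrix <- function(path) {
  tab <- read.csv(path, check.names = FALSE)
  if (!all(c("subject_id", "label") %in% names(tab))) {
    stop_invalid("feature matrix CSV must start with subject_id,label columns")
  }
  feat <- as.matrix(tab[, setdiff(names(tab), c("subject_id", "label")),
                        drop = FALSE])
  fc_dataset(feat, tab$label, tab$subject_id)
}
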