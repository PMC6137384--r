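# Edge indexing conventions and Pearson functional-connectivity extraction.
#
# All region and edge indices in this package are 1-based, following R
# convention. Edges are unordered region pairs (i, j) with i < j, laid out
# row-major over the strict upper triangle of the R x R connectivity
# matrix: (1,2), (1,3), ..., (1,R), (2,3), ..., (R-1,R).

#' Number of connectivity edges for a given region count
#'
#' A functional-connectivity feature is defined for every unordered pair of
#' distinct regions, so an atlas with `R` regions yields `R(R-1)/2` edges
#' (4005 for the standard 90-region AAL parcellation).
#'
#' @param region_count Number of atlas regions (positive integer).
#' @return Integer number of region pairs.
#' @examples
#' n_edges(90)  # 4005
#' @export
n_edges <- function(region_count) {
  if (!is_count(region_count) || region_count < 1) {
    stop_invalid("`region_count` must be a positive integer, got %s",
                 deparse(region_count))
  }
  as.integer(region_count * (region_count - 1) / 2)
}

#' Map a region pair to its flat edge index
#'
#' Edges are numbered 1..`n_edges(R)` in row-major order over the strict
#' upper triangle: (1,2) is edge 1, (1,R) is edge R-1, (R-1,R) is the last.
#'
#' @param i,j Region indices with `1 <= i < j <= R`. Vectorized.
#' @param R Region count.
#' @return Flat edge index (or vector thereof).
#' @seealso [index_to_edge()] for the inverse.
#' @export
edge_to_index <- function(i, j, R) {
  if (!is_count(R) || R < 2) stop_invalid("`R` must be an integer >= 2")
  if (length(i) != length(j)) stop_invalid("`i` and `j` must have equal length")
  bad <- !(i >= 1 & i < j & j <= R) | i != round(i) | j != round(j)
  if (any(bad)) {
    stop_invalid("invalid region pair(s): need 1 <= i < j <= R, got (%s,%s) with R=%d",
                 toString(i[bad]), toString(j[bad]), R)
  }
  as.integer((i - 1) * (2 * R - i) / 2 + (j - i))
}

#' Map a flat edge index back to its region pair
#'
#' @param index Flat edge index in 1..`n_edges(R)`. Vectorized.
#' @param R Region count.
#' @return A two-column integer matrix with columns `i`, `j` (`i < j`).
#' @export
index_to_edge <- function(index, R) {
  if (!is_count(R) || R < 2) stop_invalid("`R` must be an integer >= 2")
  m <- n_edges(R)
  if (any(index < 1 | index > m | index != round(index))) {
    stop_invalid("edge index out of range 1..%d", m)
  }
  # edge counts per row i are R-i; find the row by cumulative offsets
  offsets <- cumsum(c(0L, (R - 1L):1L))  # offsets[i] = edges before row i
  i <- findInterval(index - 1L, offsets, left.open = FALSE)
  j <- as.integer(index - offsets[i] + i)
  cbind(i = as.integer(i), j = j)
}

#' Region atlas constructor
#'
#' A parcellation table: one row per region with a name, a unique
#' abbreviation, and MNI coordinates in millimetres. The 90-region AAL
#' atlas is the reference use case; any region count works.
#'
#' @param name Character vector of region names.
#' @param abbrev Character vector of unique abbreviations.
#' @param mni Numeric matrix (regions x 3) of MNI coordinates, or NULL for
#'   all-zero placeholders.
#' @return An object of class `region_atlas`: a data.frame with columns
#'   `index`, `name`, `abbrev`, `x`, `y`, `z`.
#' @export
region_atlas <- function(name, abbrev, mni = NULL) {
  R <- length(name)
  if (R < 1) stop_invalid("atlas needs at least one region")
  if (length(abbrev) != R) stop_invalid("`name` and `abbrev` lengths differ")
  if (anyDuplicated(abbrev)) stop_invalid("atlas abbreviations must be unique")
  if (is.null(mni)) mni <- matrix(0, R, 3)
  mni <- as.matrix(mni)
  if (!all(dim(mni) == c(R, 3)) || !is.numeric(mni)) {
    stop_invalid("`mni` must be a numeric %d x 3 matrix", R)
  }
  storage.mode(mni) <- "double"
  out <- data.frame(index = seq_len(R), name = as.character(name),
                    abbrev = as.character(abbrev),
                    x = mni[, 1], y = mni[, 2], z = mni[, 3],
                    stringsAsFactors = FALSE)
  class(out) <- c("region_atlas", "data.frame")
  out
}

#' Placeholder atlas for simulations and tests
#'
#' Generates a synthetic parcellation (`R1`..`RN` with zero coordinates);
#' it carries no anatomical meaning and exists so that simulated cohorts
#' can flow through the same code paths as real atlas tables.
#'
#' @param region_count Number of regions (default 90, the AAL count).
#' @return A `region_atlas`.
#' @export
synthetic_atlas <- function(region_count = 90) {
  region_atlas(name = paste0("synthetic region ", seq_len(region_count)),
               abbrev = paste0("R", seq_len(region_count)))
}

#' Read a region atlas from a TSV file
#'
#' Expected columns: `index`, `name`, `abbreviation`, `x`, `y`, `z`
#' (MNI mm). Indices must be 1..R in order.
#'
#' @param path Path to a tab-separated atlas table with a header row.
#' @return A `region_atlas`.
#' @export
read_atlas <- function(path) {
  tab <- read.delim(path, stringsAsFactors = FALSE)
  need <- c("index", "name", "abbreviation", "x", "y", "z")
  if (!all(need %in% names(tab))) {
    stop_invalid("atlas file %s must have columns: %s", path, toString(need))
  }
  tab <- tab[order(tab$index), ]
  if (!identical(as.integer(tab$index), seq_len(nrow(tab)))) {
    stop_invalid("atlas indices must be 1..%d with no gaps", nrow(tab))
  }
  region_atlas(tab$name, tab$abbreviation, as.matrix(tab[, c("x", "y", "z")]))
}

#' @export
print.region_atlas <- function(x, ...) {
  cat(sprintf("Region atlas: %d regions, %d edges\n", nrow(x), n_edges(nrow(x))))
  print.data.frame(head(as.data.frame(x), 6), ...)
  if (nrow(x) > 6) cat(sprintf("... and %d more regions\n", nrow(x) - 6))
  invisible(x)
}

#' ROI time-series container
#'
#' One subject's regional time series: a T x R matrix (rows = timepoints,
#' columns = regions) plus a class label (+1 = control group, -1 = case
#' group).
#'
#' @param subject_id Subject identifier.
#' @param values Numeric T x R matrix, T >= 3, no missing values.
#' @param label +1 or -1.
#' @return An object of class `roi_ts`.
#' @export
roi_ts <- function(subject_id, values, label) {
  values <- as.matrix(values)
  if (!is.numeric(values) || anyNA(values)) {
    stop_invalid("time series for %s must be numeric with no missing values",
                 subject_id)
  }
  if (nrow(values) < 3) {
    stop_invalid("subject %s: need at least 3 timepoints, got %d",
                 subject_id, nrow(values))
  }
  if (!label %in% c(-1, 1)) stop_invalid("label must be +1 or -1")
  structure(list(subject_id = as.character(subject_id), values = values,
                 label = as.numeric(label)),
            class = "roi_ts")
}

#' Pearson functional connectivity of one subject
#'
#' Computes the Pearson correlation between every pair of regional time
#' series and flattens the strict upper triangle of the correlation matrix
#' into an edge-feature vector (raw r; no Fisher transform).
#'
#' @param ts An [roi_ts()] object.
#' @param atlas Optional `region_atlas`; if given, its region count must
#'   match the number of time-series columns.
#' @return Numeric vector of length `n_edges(R)`, values in \[-1, 1\],
#'   ordered by the flat edge index convention.
#' @export
compute_fc <- function(ts, atlas = NULL) {
  stopifnot(inherits(ts, "roi_ts"))
  x <- ts$values
  R <- ncol(x)
  if (!is.null(atlas) && nrow(atlas) != R) {
    stop_invalid("subject %s has %d regions but atlas has %d",
                 ts$subject_id, R, nrow(atlas))
  }
  sds <- apply(x, 2, sd)
  if (any(sds == 0)) {
    stop_invalid("subject %s: constant time series in region(s) %s; correlation undefined",
                 ts$subject_id, toString(which(sds == 0)))
  }
  cm <- cor(x)
  cm[upper.tri(cm)][flat_from_upper_tri(R)]
}

# cm[upper.tri(cm)] is column-major over the upper triangle; this
# permutation reorders it to the package's row-major edge convention.
flat_from_upper_tri <- function(R) {
  ut <- which(upper.tri(matrix(0, R, R)), arr.ind = TRUE)  # column-major (i,j)
  order(edge_to_index(ut[, 1], ut[, 2], R))
}

#' Rebuild the symmetric connectivity matrix from an edge vector
#'
#' Inverse of the flattening done by [compute_fc()]: places each edge value
#' at positions (i, j) and (j, i) and sets the diagonal to 1.
#'
#' @param fc Edge-feature vector of length `n_edges(R)`.
#' @param R Region count.
#' @return Symmetric R x R matrix with unit diagonal.
#' @export
fc_matrix <- function(fc, R) {
  if (length(fc) != n_edges(R)) {
    stop_invalid("expected %d edge values for R=%d, got %d",
                 n_edges(R), R, length(fc))
  }
  m <- diag(R)
  pairs <- index_to_edge(seq_along(fc), R)
  m[pairs] <- fc
  m[pairs[, c(2, 1), drop = FALSE]] <- fc
  m
}

#' Build a labeled subject-by-edge feature matrix from a cohort
#'
#' @param cohort List of [roi_ts()] objects sharing one region count.
#' @param atlas Optional `region_atlas` consistency check.
#' @return An [fc_dataset()]: subjects in cohort order, one column per
#'   edge feature (named `FC_i_j`), labels carried through.
#' @export
build_feature_matrix <- function(cohort, atlas = NULL) {
  if (length(cohort) < 1) stop_invalid("empty cohort")
  Rs <- vapply(cohort, function(s) ncol(s$values), integer(1))
  if (length(unique(Rs)) != 1) {
    stop_invalid("mixed region counts in cohort: %s", toString(unique(Rs)))
  }
  R <- Rs[1]
  feats <- t(vapply(cohort, compute_fc, numeric(n_edges(R)), atlas = atlas))
  colnames(feats) <- edge_feature_names(R)
  D <- fc_dataset(features = feats,
                  labels = vapply(cohort, `[[`, numeric(1), "label"),
                  subject_ids = vapply(cohort, `[[`, character(1), "subject_id"))
  # ground truth from simulated cohorts rides along for test harnesses
  attr(D, "planted_edges") <- attr(cohort, "planted_edges")
  D
}

edge_feature_names <- function(R) {
  pairs <- index_to_edge(seq_len(n_edges(R)), R)
  paste0("FC_", pairs[, 1], "_", pairs[, 2])
}
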