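# Mapping selected edge features to per-region weights and exporting
# brain-network visualization files.

#' Per-region weights of a selected edge set
#'
#' Each selected edge is incident to two regions; a region's weight is the
#' number of selected edges touching it (0 for untouched regions), so the
#' weights always sum to twice the number of selected edges. Higher weight
#' flags a region as more involved in the group contrast.
#'
#' @param selected_features Flat edge indices (a set: duplicates are an
#'   error, since a ranked selection cannot produce them).
#' @param atlas `region_atlas` (or a bare region count).
#' @return An object of class `region_weights`: a data.frame with columns
#'   `index`, `abbrev`, `x`, `y`, `z`, `weight`, one row per region in
#'   atlas order.
#' @export
region_weights <- function(selected_features, atlas) {
  if (is.numeric(atlas) && length(atlas) == 1) atlas <- synthetic_atlas(atlas)
  stopifnot(inherits(atlas, "region_atlas"))
  R <- nrow(atlas)
  selected_features <- as.integer(selected_features)
  if (anyDuplicated(selected_features)) {
    stop_invalid("duplicate edge indices in selection: %s",
                 toString(unique(selected_features[duplicated(selected_features)])))
  }
  if (length(selected_features) > 0 &&
      (min(selected_features) < 1 || max(selected_features) > n_edges(R))) {
    stop_invalid("edge index out of range 1..%d", n_edges(R))
  }
  w <- integer(R)
  if (length(selected_features) > 0) {
    pairs <- index_to_edge(selected_features, R)
    w <- tabulate(c(pairs[, 1], pairs[, 2]), nbins = R)
  }
  out <- data.frame(index = atlas$index, abbrev = atlas$abbrev,
                    x = atlas$x, y = atlas$y, z = atlas$z, weight = w,
                    stringsAsFactors = FALSE)
  class(out) <- c("region_weights", "data.frame")
  out
}

#' Filter a region-weight table to the heaviest regions
#'
#' Keeps regions whose weight is strictly greater than `min_weight`,
#' sorted by weight descending, then abbreviation.
#'
#' @param table A [region_weights()] table.
#' @param min_weight Strict lower bound (the reference analysis focuses on
#'   weight > 17).
#' @return The filtered, sorted `region_weights` subset.
#' @export
filter_regions <- function(table, min_weight = 0) {
  stopifnot(inherits(table, "region_weights"), min_weight >= 0)
  keep <- table$weight > min_weight
  out <- table[keep, , drop = FALSE]
  out <- out[order(-out$weight, out$abbrev), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("region_weights", "data.frame")
  out
}

#' Export BrainNet Viewer node/edge files
#'
#' Writes the standard whitespace-delimited text formats: a `.node` file
#' with one row per region (columns x, y, z, color, size, label; color and
#' size both default to the region weight) and a `.edge` file holding the
#' R x R symmetric 0/1 adjacency matrix of the selected edges.
#'
#' @param table A [region_weights()] table covering all regions.
#' @param selected_features Flat edge indices of the selected edges.
#' @param atlas `region_atlas` for coordinates and labels.
#' @param node_path,edge_path Output file paths.
#' @param color,size Optional per-region overrides (default: the weight).
#' @return Invisibly, c(node_path, edge_path).
#' @export
export_brainnet <- function(table, selected_features, atlas,
                            node_path, edge_path,
                            color = table$weight, size = table$weight) {
  stopifnot(inherits(table, "region_weights"), inherits(atlas, "region_atlas"))
  R <- nrow(atlas)
  if (nrow(table) != R) {
    stop_invalid("node export needs the full %d-region weight table", R)
  }
  node <- data.frame(x = atlas$x, y = atlas$y, z = atlas$z,
                     color = color, size = size,
                     label = gsub("[[:space:]]", "_", atlas$abbrev))
  write.table(node, node_path, sep = "\t", row.names = FALSE,
              col.names = FALSE, quote = FALSE)
  adj <- matrix(0L, R, R)
  if (length(selected_features) > 0) {
    pairs <- index_to_edge(as.integer(selected_features), R)
    adj[pairs] <- 1L
    adj[pairs[, c(2, 1), drop = FALSE]] <- 1L
  }
  write.table(adj, edge_path, sep = "\t", row.names = FALSE,
              col.names = FALSE, quote = FALSE)
  invisible(c(node_path, edge_path))
}

#' Write a region-weight table as CSV
#'
#' @param table A [region_weights()] table.
#' @param path Output CSV path.
#' @export
write_weights_csv <- function(table, path) {
  stopifnot(inherits(table, "region_weights"))
  write.csv(as.data.frame(table), path, row.names = FALSE)
  invisible(path)
}
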