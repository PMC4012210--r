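#' Per-cell cluster-size histogram
#'
#' Container for immuno-gold EM style quantification: for each measured
#' cell, the number of clusters observed at each cluster size. Missing
#' (cell, size) pairs mean zero.
#'
#' @param data A data.frame with columns `cell_id` (character or factor),
#'   `cluster_size` (integer >= 1) and `count` (integer >= 0).
#' @param weighting_mode How counts are interpreted when fitting:
#'   `"cluster_count"` (default; `count` is the number of clusters of that
#'   size) or `"particle_weighted"` (`count` is the number of particles,
#'   i.e. size times the number of clusters; divided by size before use).
#'
#' @return Object of class `cluster_histogram`: list with `data` (long
#'   table), `cell_ids`, `counts` (size x cell matrix), `weighting_mode`,
#'   `mean_per_size` and `sd_per_size` (cross-cell mean/SD of raw counts).
#' @export
cluster_histogram <- function(data, weighting_mode = c("cluster_count",
                                                       "particle_weighted")) {
  weighting_mode <- match.arg(weighting_mode)
  req <- c("cell_id", "cluster_size", "count")
  if (!all(req %in% names(data)))
    stop("'data' must have columns cell_id, cluster_size, count")
  data$cell_id <- as.character(data$cell_id)
  if (any(data$cluster_size < 1) || any(data$cluster_size != floor(data$cluster_size)))
    stop("'cluster_size' must be integer >= 1")
  if (any(data$count < 0) || any(data$count != floor(data$count)))
    stop("'count' must be a nonnegative integer")
  if (anyDuplicated(data[, c("cell_id", "cluster_size")]))
    stop("duplicate (cell_id, cluster_size) rows")
  cells <- sort(unique(data$cell_id))
  sizes <- seq_len(max(data$cluster_size))
  counts <- matrix(0L, nrow = length(sizes), ncol = length(cells),
                   dimnames = list(size = sizes, cell = cells))
  counts[cbind(data$cluster_size, match(data$cell_id, cells))] <-
    as.integer(data$count)
  structure(
    list(data = data[order(data$cell_id, data$cluster_size), , drop = FALSE],
         cell_ids = cells,
         counts = counts,
         weighting_mode = weighting_mode,
         mean_per_size = rowMeans(counts),
         sd_per_size = apply(counts, 1, sd)),
    class = "cluster_histogram"
  )
}

#' @export
print.cluster_histogram <- function(x, ...) {
  cat("cluster_histogram:", length(x$cell_ids), "cells,",
      sum(x$counts * as.integer(rownames(x$counts))), "particles,",
      sum(x$counts), "clusters, max size", nrow(x$counts), "\n")
  invisible(x)
}

#' Read / write the histogram TSV dialect
#'
#' Tab-separated file with header columns `cell_id`, `cluster_size`,
#' `count`; one row per (cell, size); absent pairs mean zero counts.
#'
#' @param path File path.
#' @param weighting_mode Passed to [cluster_histogram()].
#' @return `read_cluster_tsv()` returns a `cluster_histogram`;
#'   `write_cluster_tsv()` returns `path` invisibly.
#' @export
read_cluster_tsv <- function(path, weighting_mode = "cluster_count") {
  df <- read.delim(path, sep = "\t", stringsAsFactors = FALSE)
  cluster_histogram(df, weighting_mode = weighting_mode)
}

#' @rdname read_cluster_tsv
#' @param hist A `cluster_histogram`.
#' @export
write_cluster_tsv <- function(hist, path) {
  stopifnot(inherits(hist, "cluster_histogram"))
  df <- hist$data[hist$data$count > 0, c("cell_id", "cluster_size", "count")]
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

# Per-cell normalized frequencies on sizes 1..k_max, honoring the
# weighting mode (particle counts are converted to cluster counts first).
cell_frequencies <- function(hist, k_max = nrow(hist$counts)) {
  m <- hist$counts
  if (hist$weighting_mode == "particle_weighted")
    m <- m / as.integer(rownames(m))
  tot <- colSums(m)
  if (any(tot == 0)) stop("every cell must have at least one cluster")
  freq <- sweep(m, 2, tot, "/")
  freq[seq_len(k_max), , drop = FALSE]
}
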