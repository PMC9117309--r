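#' Density grid for sparsity thresholding
#'
#' The grid of graph densities at which binarized networks are built.  The
#' default (0.02 to 0.50 in steps of 0.01) yields exactly 49 densities.
#'
#' @param start,stop,step density fractions with `0 < start <= stop < 1` and
#'   `step > 0`.
#' @return Numeric vector of densities of class `density_grid`.
#' @export
density_grid <- function(start = 0.02, stop = 0.50, step = 0.01) {
  if (!(start > 0 && start <= stop && stop < 1 && step > 0))
    stop_input("invalid density grid: need 0 < start <= stop < 1, step > 0")
  k <- floor((stop - start) / step + 1e-9)
  g <- start + step * (0:k)
  class(g) <- c("density_grid", "numeric")
  g
}

# All node pairs i < j ranked for Kruskal / thresholding: by decreasing
# weight (signed by default, or absolute), ties broken lexicographically on
# (i, j) so results are identical across platforms.
ranked_edges <- function(m, rank_by = c("signed", "absolute")) {
  rank_by <- match.arg(rank_by)
  n <- nrow(m)
  ut <- which(upper.tri(m), arr.ind = TRUE)
  w <- m[ut]
  key <- if (rank_by == "signed") w else abs(w)
  ord <- order(-key, ut[, 1], ut[, 2])
  cbind(i = ut[ord, 1], j = ut[ord, 2], w = w[ord])
}

#' Maximum spanning tree of an FC matrix
#'
#' Kruskal's algorithm over the off-diagonal correlations, taking edges in
#' decreasing weight order with lexicographic tie-breaking on node indices.
#'
#' @param fc an [fc_matrix()] (or plain symmetric matrix).
#' @param rank_by rank edges by `"signed"` correlation (default, the literal
#'   decreasing-correlation rule) or `"absolute"` magnitude.
#' @return Integer matrix with `n - 1` rows and columns `i`, `j` (`i < j`).
#' @export
max_spanning_tree <- function(fc, rank_by = c("signed", "absolute")) {
  m <- if (inherits(fc, "fc_matrix")) fc$matrix else as.matrix(fc)
  n <- nrow(m)
  if (n < 2) stop_input("need at least 2 nodes for a spanning tree, got %d", n)
  re <- ranked_edges(m, rank_by)
  kruskal_mark(re, n)$tree
}

# Marks, in ranked order, which edges Kruskal accepts into the tree.
kruskal_mark <- function(re, n) {
  parent <- seq_len(n)
  find <- function(x) {
    while (parent[x] != x) {
      parent[x] <<- parent[parent[x]]
      x <- parent[x]
    }
    x
  }
  in_tree <- logical(nrow(re))
  got <- 0L
  for (k in seq_len(nrow(re))) {
    a <- find(re[k, 1]); b <- find(re[k, 2])
    if (a != b) {
      parent[a] <- b
      in_tree[k] <- TRUE
      got <- got + 1L
      if (got == n - 1L) break
    }
  }
  list(tree = unname(re[in_tree, c(1, 2), drop = FALSE]), in_tree = in_tree)
}

#' Build the nested graph series across a density grid
#'
#' For each density `d`, the graph has `round(d * n(n-1)/2)` edges (round
#' half to even): the maximum spanning tree plus the globally
#' highest-correlation non-tree edges.  All graphs are connected, contain the
#' MST, and are nested along the grid; weights are discarded (binarized
#' networks).
#'
#' @param fc an [fc_matrix()].
#' @param grid a [density_grid()].
#' @param rank_by see [max_spanning_tree()].
#' @return An object of class `graph_series`: list with `subject_id`,
#'   `n_nodes`, `densities`, `edge_counts`, `mst_edges` (matrix), and
#'   `extra_edges` (non-tree edges in rank order).  Use [series_edges()] /
#'   [series_graph()] to materialize individual graphs.
#' @export
build_graph_series <- function(fc, grid = density_grid(),
                               rank_by = c("signed", "absolute")) {
  stopifnot(inherits(fc, "fc_matrix"))
  m <- fc$matrix
  n <- nrow(m)
  n_pairs <- n * (n - 1) / 2
  counts <- round(grid * n_pairs)
  if (counts[1] < n - 1)
    stop_input(paste0("edge budget %d at density %.4f is below the MST size %d; ",
                      "minimum feasible density is %.4f"),
               counts[1], grid[1], n - 1, (n - 1) / n_pairs)
  re <- ranked_edges(m, rank_by)
  km <- kruskal_mark(re, n)
  extra <- unname(re[!km$in_tree, c(1, 2), drop = FALSE])
  structure(list(subject_id = fc$subject_id, n_nodes = n,
                 densities = as.numeric(grid),
                 edge_counts = as.integer(counts),
                 mst_edges = km$tree, extra_edges = extra),
            class = "graph_series")
}

#' Materialize one graph of a series
#'
#' @param series a [build_graph_series()] result.
#' @param index position in the density grid.
#' @return `series_edges`: integer edge matrix (columns `i`, `j`);
#'   `series_graph`: the same graph as an `igraph` object with
#'   `series$n_nodes` vertices.
#' @export
series_edges <- function(series, index) {
  stopifnot(inherits(series, "graph_series"))
  if (index < 1 || index > length(series$densities))
    stop_input("index %d outside the density grid (1..%d)", index,
               length(series$densities))
  k_extra <- series$edge_counts[index] - nrow(series$mst_edges)
  rbind(series$mst_edges,
        series$extra_edges[seq_len(k_extra), , drop = FALSE])
}

#' @rdname series_edges
#' @export
series_graph <- function(series, index) {
  e <- series_edges(series, index)
  igraph::make_graph(edges = as.vector(t(e)), n = series$n_nodes,
                     directed = FALSE)
}

#' @export
print.graph_series <- function(x, ...) {
  cat(sprintf("<graph_series> subject '%s', %d nodes, %d densities (%.2f..%.2f)\n",
              x$subject_id, x$n_nodes, length(x$densities),
              min(x$densities), max(x$densities)))
  invisible(x)
}

#' Export a graph series as edge lists plus a JSON manifest
#'
#' Writes one two-column TSV per density (1-based ROI ids) and a
#' `manifest.json` recording subject id, density, edge count and a simple
#' order-independent checksum per graph.
#'
#' @param series a `graph_series`.
#' @param dir output directory.
#' @return `dir`, invisibly.
#' @export
write_graph_series <- function(series, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  entries <- vector("list", length(series$densities))
  for (k in seq_along(series$densities)) {
    e <- series_edges(series, k)
    f <- file.path(dir, sprintf("%s_d%.2f.tsv", series$subject_id,
                                series$densities[k]))
    write.table(e, f, sep = "\t", quote = FALSE, row.names = FALSE,
                col.names = c("i", "j"))
    entries[[k]] <- list(subject_id = series$subject_id,
                         density = series$densities[k],
                         n_edges = nrow(e),
                         checksum = sum((e[, 1] * 131 + e[, 2]) %% 982451653),
                         file = basename(f))
  }
  jsonlite::write_json(entries, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
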