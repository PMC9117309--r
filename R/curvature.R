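#' Forman-Ricci curvature of graph edges
#'
#' For an unweighted edge \eqn{e = (u, v)} the classical combinatorial form
#' is \eqn{F(e) = 4 - deg(u) - deg(v)}; the augmented form adds
#' \eqn{3 t(e)}, where \eqn{t(e)} is the number of triangles containing the
#' edge, making the curvature sensitive to local clustering.  The augmented
#' form is the default used throughout the pipeline.
#'
#' @param graph an `igraph` object (undirected, simple).
#' @param variant `"augmented"` (default) or `"classical"`.
#' @return `frc_edges`: numeric vector of per-edge curvatures, in
#'   `igraph::as_edgelist` order; `frc_edge`: the single value for edge
#'   `(u, v)` (error if the edge is absent).
#' @export
frc_edges <- function(graph, variant = c("augmented", "classical")) {
  variant <- match.arg(variant)
  el <- igraph::as_edgelist(graph, names = FALSE)
  deg <- igraph::degree(graph)
  val <- 4 - deg[el[, 1]] - deg[el[, 2]]
  if (variant == "augmented" && nrow(el)) {
    a <- igraph::as_adjacency_matrix(graph, sparse = TRUE)
    a2 <- a %*% a
    val <- val + 3 * as.numeric(a2[el])
  }
  as.numeric(val)
}

#' @rdname frc_edges
#' @param u,v endpoints of a single edge.
#' @export
frc_edge <- function(graph, u, v, variant = c("augmented", "classical")) {
  eid <- igraph::get_edge_ids(graph, c(u, v))
  if (eid == 0) stop_input("edge (%s, %s) not present in graph", u, v)
  frc_edges(graph, variant)[eid]
}

#' Ollivier-Ricci curvature of graph edges
#'
#' \deqn{\kappa(u, v) = 1 - W_1(m_u, m_v) / d(u, v)} where \eqn{m_x} places
#' mass `alpha` on \eqn{x} and spreads \eqn{(1 - alpha)} uniformly over its
#' neighbours, \eqn{d} is the shortest-path hop count, and \eqn{W_1} is the
#' Wasserstein-1 distance computed as an exact transportation optimum
#' ([min_cost_transport()]).  For an edge, \eqn{d(u, v) = 1}.
#'
#' @param graph connected undirected `igraph` object.
#' @param alpha idleness in `[0, 1)`: probability mass retained at the base
#'   node (default 0, the non-lazy convention).
#' @return `orc_edges`: numeric per-edge curvatures in edge-list order;
#'   `orc_edge`: the single value for `(u, v)`.
#' @export
orc_edges <- function(graph, alpha = 0) {
  if (alpha < 0 || alpha >= 1)
    stop_input("idleness alpha must be in [0, 1), got %s", alpha)
  el <- igraph::as_edgelist(graph, names = FALSE)
  if (!nrow(el)) return(numeric(0))
  if (igraph::components(graph)$no > 1)
    stop_input("graph must be connected for ORC (finite ground distances)")
  D <- igraph::distances(graph)
  adj <- igraph::as_adj_list(graph)
  vapply(seq_len(nrow(el)), function(k) {
    u <- el[k, 1]; v <- el[k, 2]
    nu <- as.integer(adj[[u]]); nv <- as.integer(adj[[v]])
    if (alpha > 0) {
      su <- c(u, nu); sv <- c(v, nv)
      mu <- c(alpha, rep((1 - alpha) / length(nu), length(nu)))
      mv <- c(alpha, rep((1 - alpha) / length(nv), length(nv)))
    } else {
      su <- nu; sv <- nv
      mu <- rep(1 / length(nu), length(nu))
      mv <- rep(1 / length(nv), length(nv))
    }
    w1 <- min_cost_transport(mu, mv, D[su, sv, drop = FALSE])
    1 - w1 / D[u, v]
  }, numeric(1))
}

#' @rdname orc_edges
#' @param u,v endpoints of a single edge.
#' @export
orc_edge <- function(graph, u, v, alpha = 0) {
  eid <- igraph::get_edge_ids(graph, c(u, v))
  if (eid == 0) stop_input("edge (%s, %s) not present in graph", u, v)
  orc_edges(graph, alpha)[eid]
}

#' Node curvature by incident-edge summation
#'
#' Node Ricci curvature is the sum of the curvatures of the edges incident
#' on the node (so the total over nodes is exactly twice the total over
#' edges).
#'
#' @param edge_values numeric per-edge curvature in `igraph::as_edgelist`
#'   order (as returned by [frc_edges()] / [orc_edges()]).
#' @param graph the `igraph` object the values belong to.
#' @return Numeric vector of per-node curvatures (isolated nodes get 0).
#' @export
node_curvature <- function(edge_values, graph) {
  el <- igraph::as_edgelist(graph, names = FALSE)
  if (length(edge_values) != nrow(el) || anyNA(edge_values))
    stop_input("edge_values must cover all %d edges without NAs", nrow(el))
  n <- igraph::vcount(graph)
  out <- numeric(n)
  for (k in seq_len(nrow(el))) {
    out[el[k, 1]] <- out[el[k, 1]] + edge_values[k]
    out[el[k, 2]] <- out[el[k, 2]] + edge_values[k]
  }
  out
}

#' Average edge curvature
#'
#' @param edge_values non-empty numeric vector of per-edge curvatures.
#' @return Arithmetic mean.
#' @export
average_edge_curvature <- function(edge_values) {
  if (!length(edge_values)) stop_input("empty edge set")
  mean(edge_values)
}

#' Per-edge and per-node curvature table for one graph
#'
#' @param graph connected undirected `igraph` object.
#' @param frc_variant Forman variant, see [frc_edges()].
#' @param orc compute Ollivier-Ricci curvature as well (slower)?
#' @param alpha ORC idleness, see [orc_edges()].
#' @return List of class `curvature_table` with data.frames `edges`
#'   (`u`, `v`, `frc` and optionally `orc`) and `nodes` (`node`, `frc_node`,
#'   optionally `orc_node`).
#' @export
curvature_table <- function(graph, frc_variant = "augmented", orc = FALSE,
                            alpha = 0) {
  el <- igraph::as_edgelist(graph, names = FALSE)
  frc <- frc_edges(graph, frc_variant)
  edges <- data.frame(u = el[, 1], v = el[, 2], frc = frc)
  nodes <- data.frame(node = seq_len(igraph::vcount(graph)),
                      frc_node = node_curvature(frc, graph))
  if (orc) {
    edges$orc <- orc_edges(graph, alpha)
    nodes$orc_node <- node_curvature(edges$orc, graph)
  }
  structure(list(edges = edges, nodes = nodes), class = "curvature_table")
}

#' Export a curvature table as TSV files
#'
#' Writes `<prefix>_edges.tsv` and `<prefix>_nodes.tsv`.
#'
#' @param ct a [curvature_table()].
#' @param prefix path prefix.
#' @return `prefix`, invisibly.
#' @export
write_curvature_table <- function(ct, prefix) {
  write.table(ct$edges, paste0(prefix, "_edges.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  write.table(ct$nodes, paste0(prefix, "_nodes.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  invisible(prefix)
}
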