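#' Global measures of a binarized graph
#'
#' The six standard global measures of the pipeline, under the usual binary
#' conventions:
#' * average clustering: Watts-Strogatz local clustering averaged over nodes,
#'   with nodes of degree < 2 contributing 0;
#' * modularity: Newman-Girvan modularity of the partition found by the
#'   configured community method (greedy agglomerative maximization by
#'   default, which is deterministic);
#' * average shortest path length: mean hop count over all node pairs;
#' * average node betweenness: mean betweenness normalized by
#'   \eqn{(n-1)(n-2)/2};
#' * global efficiency: mean of \eqn{1/d(i,j)} over pairs;
#' * average local efficiency: mean over nodes of the global efficiency of
#'   the open neighbourhood subgraph.
#'
#' @param graph connected undirected `igraph` with >= 3 nodes.
#' @param community community-detection method for modularity:
#'   `"fast_greedy"` (default, deterministic) or `"louvain"`.
#' @return Named list with `avg_clustering`, `modularity`,
#'   `avg_shortest_path`, `avg_node_betweenness`, `global_efficiency`,
#'   `avg_local_efficiency`.
#' @export
global_measures <- function(graph, community = c("fast_greedy", "louvain")) {
  community <- match.arg(community)
  n <- igraph::vcount(graph)
  if (n < 3) stop_input("need >= 3 nodes, got %d", n)
  if (igraph::components(graph)$no > 1)
    stop_input("graph must be connected")
  cl <- switch(community,
               fast_greedy = igraph::cluster_fast_greedy(graph),
               louvain = igraph::cluster_louvain(graph))
  list(
    avg_clustering = mean(igraph::transitivity(graph, type = "local",
                                               isolates = "zero")),
    modularity = igraph::modularity(graph, igraph::membership(cl)),
    avg_shortest_path = igraph::mean_distance(graph),
    avg_node_betweenness = mean(igraph::betweenness(graph, normalized = TRUE)),
    global_efficiency = igraph::global_efficiency(graph),
    avg_local_efficiency = igraph::average_local_efficiency(graph)
  )
}

#' Nodal measures of a binarized graph
#'
#' Per-node Watts-Strogatz clustering coefficient (0 for degree < 2) and
#' betweenness centrality normalized by \eqn{(n-1)(n-2)/2}.
#'
#' @param graph connected undirected `igraph`.
#' @return data.frame with columns `node`, `clustering`, `betweenness`.
#' @export
nodal_measures <- function(graph) {
  if (igraph::components(graph)$no > 1)
    stop_input("graph must be connected")
  data.frame(
    node = seq_len(igraph::vcount(graph)),
    clustering = igraph::transitivity(graph, type = "local",
                                      isolates = "zero"),
    betweenness = igraph::betweenness(graph, normalized = TRUE)
  )
}
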