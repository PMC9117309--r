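GLOBAL_MEASURE_NAMES <- c("frc", "orc", "avg_clustering", "modularity",
                          "avg_shortest_path", "avg_node_betweenness",
                          "global_efficiency", "avg_local_efficiency")
NODAL_MEASURE_NAMES <- c("frc", "orc", "clustering", "betweenness")

#' Per-subject measures across the density grid
#'
#' Builds the subject's nested graph series and evaluates the requested
#' global measures at every density and the requested nodal measures as
#' AUCs over the density axis.  `"frc"` / `"orc"` denote average edge (or
#' per-node) Forman-Ricci and Ollivier-Ricci curvature.
#'
#' @param fc an [fc_matrix()].
#' @param grid a [density_grid()].
#' @param global character subset of
#'   `c("frc", "orc", "avg_clustering", "modularity", "avg_shortest_path",
#'   "avg_node_betweenness", "global_efficiency", "avg_local_efficiency")`.
#' @param nodal character subset of
#'   `c("frc", "orc", "clustering", "betweenness")`.
#' @param frc_variant see [frc_edges()].
#' @param alpha ORC idleness, see [orc_edges()].
#' @param rank_by edge-ranking rule, see [max_spanning_tree()].
#' @return List with `global` (matrix: density x measure), `nodal_auc`
#'   (matrix: node x measure) and `series` (the [build_graph_series()]).
#' @export
subject_measures <- function(fc, grid = density_grid(),
                             global = c("frc", "avg_clustering", "modularity"),
                             nodal = "frc",
                             frc_variant = "augmented", alpha = 0,
                             rank_by = "signed") {
  global <- if (length(global))
    match.arg(global, GLOBAL_MEASURE_NAMES, several.ok = TRUE) else character(0)
  nodal <- if (length(nodal))
    match.arg(nodal, NODAL_MEASURE_NAMES, several.ok = TRUE) else character(0)
  series <- build_graph_series(fc, grid, rank_by)
  nd <- length(grid)
  gmat <- matrix(NA_real_, nd, length(global),
                 dimnames = list(NULL, global))
  nmat_d <- array(NA_real_, c(series$n_nodes, nd, length(nodal)),
                  dimnames = list(NULL, NULL, nodal))
  need_std_global <- setdiff(global, c("frc", "orc"))
  for (k in seq_len(nd)) {
    g <- series_graph(series, k)
    if ("frc" %in% global || "frc" %in% nodal) {
      fe <- frc_edges(g, frc_variant)
      if ("frc" %in% global) gmat[k, "frc"] <- average_edge_curvature(fe)
      if ("frc" %in% nodal) nmat_d[, k, "frc"] <- node_curvature(fe, g)
    }
    if ("orc" %in% global || "orc" %in% nodal) {
      oe <- orc_edges(g, alpha)
      if ("orc" %in% global) gmat[k, "orc"] <- average_edge_curvature(oe)
      if ("orc" %in% nodal) nmat_d[, k, "orc"] <- node_curvature(oe, g)
    }
    if (length(need_std_global)) {
      gm <- global_measures(g)
      for (nm in need_std_global) gmat[k, nm] <- gm[[nm]]
    }
    if (any(c("clustering", "betweenness") %in% nodal)) {
      nm <- nodal_measures(g)
      if ("clustering" %in% nodal) nmat_d[, k, "clustering"] <- nm$clustering
      if ("betweenness" %in% nodal) nmat_d[, k, "betweenness"] <- nm$betweenness
    }
  }
  nmat <- matrix(NA_real_, series$n_nodes, length(nodal),
                 dimnames = list(NULL, nodal))
  for (nm in nodal)
    nmat[, nm] <- apply(nmat_d[, , nm, drop = FALSE], 1,
                        function(v) auc_over_densities(as.numeric(v), grid))
  list(global = gmat, nodal_auc = nmat, series = series)
}

#' Measure tensors for a whole cohort
#'
#' Runs [subject_measures()] for every subject and assembles
#' [measure_tensor()] objects ready for [compare_global()] /
#' [compare_nodal()].
#'
#' @param fc_list list of [fc_matrix()] objects.
#' @param groups group label per subject.
#' @param grid,global,nodal,frc_variant,alpha,rank_by passed to
#'   [subject_measures()].
#' @return List with `global` (named list of subject-by-density tensors, one
#'   per global measure) and `nodal_auc` (named list of subject-by-node AUC
#'   tensors, one per nodal measure).
#' @export
cohort_measures <- function(fc_list, groups, grid = density_grid(),
                            global = c("frc", "avg_clustering", "modularity"),
                            nodal = "frc",
                            frc_variant = "augmented", alpha = 0,
                            rank_by = "signed") {
  if (length(groups) != length(fc_list))
    stop_input("groups length %d != number of subjects %d",
               length(groups), length(fc_list))
  per <- lapply(fc_list, subject_measures, grid = grid, global = global,
                nodal = nodal, frc_variant = frc_variant, alpha = alpha,
                rank_by = rank_by)
  ids <- vapply(fc_list, function(f) f$subject_id, character(1))
  gt <- lapply(stats::setNames(global, global), function(nm) {
    v <- t(vapply(per, function(p) p$global[, nm], numeric(length(grid))))
    measure_tensor(v, as.numeric(grid), ids, groups)
  })
  nt <- lapply(stats::setNames(nodal, nodal), function(nm) {
    nn <- nrow(per[[1]]$nodal_auc)
    v <- t(vapply(per, function(p) p$nodal_auc[, nm], numeric(nn)))
    measure_tensor(v, seq_len(nn), ids, groups)
  })
  list(global = gt, nodal_auc = nt)
}

#' Write comparison results and a JSON summary
#'
#' @param comparison result of [compare_global()] or [compare_nodal()].
#' @param path output TSV path.
#' @return `path`, invisibly.
#' @export
write_comparison <- function(comparison, path) {
  write.table(comparison, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
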