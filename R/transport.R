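#' Exact optimal-transport cost between two discrete measures
#'
#' Solves the balanced transportation problem
#' \deqn{\min \sum_{ij} c_{ij} x_{ij},\quad \sum_j x_{ij} = s_i,\ \sum_i x_{ij} = d_j,\ x \ge 0}
#' by successive shortest augmenting paths on the bipartite flow network
#' (Bellman-Ford label correction, which tolerates the negative residual-arc
#' costs).  With probability measures as marginals the optimum is the
#' Wasserstein-1 distance under ground cost `cost`.  Exact for the small,
#' integer-cost problems arising in Ollivier-Ricci curvature, where supports
#' are neighbourhoods and costs are shortest-path hop counts.
#'
#' @param supply,demand non-negative numeric vectors with equal sums.
#' @param cost numeric cost matrix, `length(supply)` rows by
#'   `length(demand)` columns; must be finite.
#' @return The optimal transport cost (a single number).
#' @export
min_cost_transport <- function(supply, demand, cost) {
  cost <- as.matrix(cost)
  m <- length(supply); n <- length(demand)
  if (nrow(cost) != m || ncol(cost) != n)
    stop_input("cost must be %d x %d, got %d x %d", m, n, nrow(cost), ncol(cost))
  if (any(supply < 0) || any(demand < 0))
    stop_input("negative mass in supply or demand")
  if (!all(is.finite(cost)))
    stop_input("non-finite ground cost (disconnected supports?)")
  tot <- sum(supply)
  if (abs(tot - sum(demand)) > 1e-9 * max(1, tot))
    stop_input("unbalanced transport problem: supply %g vs demand %g",
               tot, sum(demand))
  tol <- 1e-12 * max(1, tot)
  flow <- matrix(0, m, n)
  srem <- supply; drem <- demand
  guard <- 0L
  while (sum(srem) > tol) {
    guard <- guard + 1L
    if (guard > 4L * (m * n + m + n))
      stop("transport solver failed to terminate", call. = FALSE)
    # shortest-path labels over supply nodes (ds) and demand nodes (dd)
    ds <- ifelse(srem > tol, 0, Inf)
    dd <- rep(Inf, n)
    pred_d <- rep(NA_integer_, n)   # supply feeding demand j on the path
    pred_s <- rep(NA_integer_, m)   # demand feeding supply i via residual
    from_src <- srem > tol          # whether ds[i] is the source label 0
    repeat {
      changed <- FALSE
      for (i in seq_len(m)) {
        if (!is.finite(ds[i])) next
        nv <- ds[i] + cost[i, ]
        upd <- nv < dd - 1e-13
        if (any(upd)) {
          dd[upd] <- nv[upd]; pred_d[upd] <- i; changed <- TRUE
        }
      }
      for (j in seq_len(n)) {
        if (!is.finite(dd[j])) next
        has <- which(flow[, j] > tol)
        if (length(has)) {
          nv <- dd[j] - cost[has, j]
          upd <- nv < ds[has] - 1e-13
          if (any(upd)) {
            ds[has[upd]] <- nv[upd]
            pred_s[has[upd]] <- j
            from_src[has[upd]] <- FALSE
            changed <- TRUE
          }
        }
      }
      if (!changed) break
    }
    open <- which(drem > tol & is.finite(dd))
    if (!length(open))
      stop("transport solver: no augmenting path (infeasible)", call. = FALSE)
    jt <- open[which.min(dd[open])]
    # reconstruct the alternating path back to a source supply
    path_i <- integer(0); path_j <- jt
    i <- pred_d[jt]
    while (TRUE) {
      path_i <- c(i, path_i)
      if (from_src[i]) break
      j <- pred_s[i]
      path_j <- c(j, path_j)
      i <- pred_d[j]
    }
    # bottleneck: source remainder, sink remainder, residual flows on path
    bn <- min(srem[path_i[1]], drem[jt])
    if (length(path_j) > 1) {
      res <- flow[cbind(path_i[-1], path_j[-length(path_j)])]
      bn <- min(bn, res)
    }
    # augment: forward arcs (i_k -> j_k) gain, residual arcs lose
    flow[cbind(path_i, path_j)] <- flow[cbind(path_i, path_j)] + bn
    if (length(path_j) > 1) {
      idx <- cbind(path_i[-1], path_j[-length(path_j)])
      flow[idx] <- flow[idx] - bn
    }
    srem[path_i[1]] <- srem[path_i[1]] - bn
    drem[jt] <- drem[jt] - bn
  }
  sum(flow * cost)
}
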