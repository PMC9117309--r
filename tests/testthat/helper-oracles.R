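# Independent oracles used across the suite.  Each deliberately re-derives
# its quantity by a different route than the package implementation.

# ---- dense two-phase simplex (Bland's rule) -------------------------------
# min c'x  s.t.  A x = b, x >= 0.  Small problems only.
lp_simplex <- function(cost, A, b, tol = 1e-9) {
  m <- nrow(A); n <- ncol(A)
  flip <- b < 0
  A[flip, ] <- -A[flip, , drop = FALSE]; b[flip] <- -b[flip]
  pivot <- function(T, basis, i, j) {
    T[i, ] <- T[i, ] / T[i, j]
    for (r in seq_len(nrow(T))) if (r != i && abs(T[r, j]) > 0)
      T[r, ] <- T[r, ] - T[r, j] * T[i, ]
    basis[i] <- j
    list(T = T, basis = basis)
  }
  run <- function(T, basis, costs) {
    nv <- ncol(T) - 1
    repeat {
      cB <- costs[basis]
      red <- costs[seq_len(nv)] - as.vector(cB %*% T[, seq_len(nv), drop = FALSE])
      ent <- which(red < -tol)
      if (!length(ent)) return(list(T = T, basis = basis))
      j <- min(ent)                                  # Bland: entering
      col <- T[, j]
      pos <- which(col > tol)
      if (!length(pos)) stop("unbounded LP")
      ratio <- T[pos, nv + 1] / col[pos]
      cand <- pos[ratio <= min(ratio) + tol]
      i <- cand[which.min(basis[cand])]              # Bland: leaving
      r <- pivot(T, basis, i, j)
      T <- r$T; basis <- r$basis
    }
  }
  # phase 1
  T <- cbind(A, diag(m), b)
  basis <- n + seq_len(m)
  r1 <- run(T, basis, c(rep(0, n), rep(1, m)))
  if (sum(c(rep(0, n), rep(1, m))[r1$basis] * r1$T[, ncol(T)]) > 1e-7)
    stop("infeasible LP")
  T <- r1$T; basis <- r1$basis
  for (i in which(basis > n)) {                      # drive artificials out
    j <- which(abs(T[i, seq_len(n)]) > tol)
    if (length(j)) {
      r <- pivot(T, basis, i, j[1]); T <- r$T; basis <- r$basis
    }
  }
  keep <- basis <= n
  T <- T[keep, c(seq_len(n), ncol(T)), drop = FALSE]
  basis <- basis[keep]
  r2 <- run(T, basis, cost)
  x <- numeric(n)
  x[r2$basis] <- r2$T[, ncol(r2$T)]
  list(value = sum(cost * x), x = x)
}

# W1 between the two marginals via the simplex (column-major variable order)
lp_transport_oracle <- function(mu, mv, cost) {
  m <- length(mu); n <- length(mv)
  nv <- m * n
  A <- matrix(0, m + n - 1, nv)
  for (i in seq_len(m)) A[i, (seq_len(n) - 1) * m + i] <- 1
  for (j in seq_len(n - 1)) A[m + j, (j - 1) * m + seq_len(m)] <- 1
  b <- c(mu, mv[-n])
  lp_simplex(as.vector(cost), A, b)$value
}

# ORC re-derived from scratch: measures, hop distances, simplex W1.
orc_oracle <- function(graph, u, v, alpha = 0) {
  D <- igraph::distances(graph)
  nu <- as.integer(igraph::neighbors(graph, u))
  nv <- as.integer(igraph::neighbors(graph, v))
  if (alpha > 0) {
    su <- c(u, nu); sv <- c(v, nv)
    mu <- c(alpha, rep((1 - alpha) / length(nu), length(nu)))
    mv <- c(alpha, rep((1 - alpha) / length(nv), length(nv)))
  } else {
    su <- nu; sv <- nv
    mu <- rep(1 / length(nu), length(nu))
    mv <- rep(1 / length(nv), length(nv))
  }
  1 - lp_transport_oracle(mu, mv, D[su, sv, drop = FALSE]) / D[u, v]
}

# ---- brute-force spanning trees -------------------------------------------
# All spanning trees of the complete graph on n nodes (tiny n only).
best_spanning_tree_weight <- function(w) {
  n <- nrow(w)
  pairs <- t(combn(n, 2))
  best <- -Inf
  for (s in combn(nrow(pairs), n - 1, simplify = FALSE)) {
    e <- pairs[s, , drop = FALSE]
    g <- igraph::make_graph(edges = as.vector(t(e)), n = n, directed = FALSE)
    if (igraph::components(g)$no == 1)
      best <- max(best, sum(w[e]))
  }
  best
}

# ---- modularity by exhaustive partition enumeration -----------------------
set_partitions <- function(n) {
  if (n == 1) return(list(list(1L)))
  out <- list()
  for (p in set_partitions(n - 1)) {
    for (k in seq_along(p)) {
      q <- p; q[[k]] <- c(q[[k]], n)
      out[[length(out) + 1]] <- q
    }
    out[[length(out) + 1]] <- c(p, list(n))
  }
  out
}

modularity_value <- function(el, n, membership) {
  m <- nrow(el)
  deg <- tabulate(c(el[, 1], el[, 2]), n)
  q <- 0
  for (c_ in unique(membership)) {
    nodes <- which(membership == c_)
    lc <- sum(el[, 1] %in% nodes & el[, 2] %in% nodes)
    dc <- sum(deg[nodes])
    q <- q + lc / m - (dc / (2 * m))^2
  }
  q
}

max_modularity_oracle <- function(el, n) {
  best <- -Inf
  for (p in set_partitions(n)) {
    mem <- integer(n)
    for (k in seq_along(p)) mem[p[[k]]] <- k
    best <- max(best, modularity_value(el, n, mem))
  }
  best
}

# ---- betweenness / efficiency by simple-path enumeration ------------------
all_simple_paths_between <- function(adj, s, t) {
  out <- list()
  walk <- function(path) {
    last <- path[length(path)]
    if (last == t) {
      out[[length(out) + 1]] <<- path
      return()
    }
    for (nb in adj[[last]]) if (!nb %in% path) walk(c(path, nb))
  }
  walk(s)
  out
}

betweenness_oracle <- function(graph) {
  n <- igraph::vcount(graph)
  adj <- lapply(igraph::as_adj_list(graph), as.integer)
  btw <- numeric(n)
  for (s in seq_len(n - 1)) for (t in (s + 1):n) {
    paths <- all_simple_paths_between(adj, s, t)
    len <- vapply(paths, length, integer(1))
    sp <- paths[len == min(len)]
    for (v in seq_len(n)) {
      if (v == s || v == t) next
      onv <- sum(vapply(sp, function(p) v %in% p, logical(1)))
      btw[v] <- btw[v] + onv / length(sp)
    }
  }
  btw / ((n - 1) * (n - 2) / 2)
}

# ---- misc -----------------------------------------------------------------
pearson_oracle <- function(x, y) {
  xm <- x - mean(x); ym <- y - mean(y)
  sum(xm * ym) / sqrt(sum(xm^2) * sum(ym^2))
}

# the connected small-graph suite: all graphs on <= `max_n` nodes up to
# isomorphism, via the graph atlas (numbers 1..208 cover 1..6 nodes)
small_graph_suite <- function(max_n = 6, min_n = 2) {
  out <- list()
  for (i in 1:208) {
    g <- igraph::graph_from_atlas(i)
    if (igraph::vcount(g) < min_n || igraph::vcount(g) > max_n) next
    if (igraph::ecount(g) == 0) next
    if (igraph::components(g)$no != 1) next
    out[[length(out) + 1]] <- g
  }
  out
}

# quick synthetic FC matrix (valid correlation matrix) for graph tests
random_fc <- function(n, seed, subject_id = "s") {
  spec <- cohort_spec(n_rois = n, n_subjects_per_group = 1, n_blocks = 2,
                      seed = seed)
  generate_cohort(spec)$fc[[1]]
}
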