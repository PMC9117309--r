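g_path4 <- igraph::make_graph(edges = c(1, 2, 2, 3, 3, 4), directed = FALSE)

test_that("classical and augmented FRC match their combinatorial formulas", {
  k2 <- igraph::make_graph(edges = c(1, 2), directed = FALSE)
  expect_equal(frc_edge(k2, 1, 2, "classical"), 2)          # 4 - 1 - 1
  expect_equal(frc_edge(g_path4, 2, 3, "classical"), 0)     # 4 - 2 - 2
  k3 <- igraph::make_full_graph(3)
  expect_equal(frc_edge(k3, 1, 2, "augmented"), 3)          # 4 - 2 - 2 + 3
  expect_equal(frc_edge(k3, 1, 2, "classical"), 0)
  expect_error(frc_edge(g_path4, 1, 4), "not present")
})

test_that("FRC matches a direct degree/triangle recomputation on the suite", {
  for (g in small_graph_suite()) {
    el <- igraph::as_edgelist(g, names = FALSE)
    adj <- lapply(igraph::as_adj_list(g), as.integer)
    deg <- igraph::degree(g)
    for (variant in c("classical", "augmented")) {
      got <- frc_edges(g, variant)
      want <- vapply(seq_len(nrow(el)), function(k) {
        u <- el[k, 1]; v <- el[k, 2]
        tri <- length(intersect(adj[[u]], adj[[v]]))
        4 - deg[u] - deg[v] + if (variant == "augmented") 3 * tri else 0
      }, numeric(1))
      expect_identical(got, want)
    }
    # classical FRC of a simple-graph edge never exceeds 2
    expect_true(all(frc_edges(g, "classical") <= 2))
  }
})

test_that("ORC reproduces derived closed values", {
  expect_equal(orc_edge(igraph::make_full_graph(3), 1, 2), 0.5,
               tolerance = 1e-9)
  expect_equal(orc_edge(igraph::make_full_graph(4), 1, 2), 2 / 3,
               tolerance = 1e-9)
  expect_equal(orc_edge(g_path4, 2, 3), 0, tolerance = 1e-9)
  for (n in 6:9) {
    cn <- igraph::make_ring(n)
    expect_equal(orc_edges(cn), rep(0, n), tolerance = 1e-9)
  }
})

test_that("ORC matches values frozen from an external exact LP solver", {
  # reference values computed once with scipy.optimize.linprog (HiGHS)
  frozen <- list(
    list(g = igraph::make_full_graph(3), e = c(1, 2), a = 0.5,
         want = 0.75),
    list(g = igraph::make_star(5, mode = "undirected"), e = c(1, 2), a = 0,
         want = 0.0),
    list(g = igraph::make_star(5, mode = "undirected"), e = c(1, 2), a = 0.5,
         want = 0.25),
    list(g = igraph::make_graph(edges = c(1, 2, 1, 5, 2, 3, 2, 4, 2, 5,
                                          3, 4, 3, 5, 4, 5),
                                directed = FALSE), e = c(3, 4), a = 0,
         want = 2 / 3),
    list(g = igraph::make_graph(edges = c(1, 2, 1, 3, 1, 4, 1, 5, 2, 4,
                                          4, 5),
                                directed = FALSE), e = c(4, 5), a = 0.5,
         want = 0.5),
    list(g = igraph::make_graph(edges = c(1, 2, 2, 4, 2, 5, 3, 5, 4, 5),
                                directed = FALSE), e = c(2, 4), a = 0.5,
         want = 0.416666666666667))
  for (cs in frozen)
    expect_equal(orc_edge(cs$g, cs$e[1], cs$e[2], alpha = cs$a), cs$want,
                 tolerance = 1e-9)
})

test_that("ORC equals the in-suite simplex LP oracle on all small graphs", {
  for (g in small_graph_suite(max_n = 5)) {
    el <- igraph::as_edgelist(g, names = FALSE)
    got <- orc_edges(g)
    for (k in seq_len(nrow(el)))
      expect_equal(got[k], orc_oracle(g, el[k, 1], el[k, 2]),
                   tolerance = 1e-9)
  }
})

test_that("ORC bounds, idleness validation and edge checks hold", {
  for (g in small_graph_suite(max_n = 5)) {
    v <- orc_edges(g)
    expect_true(all(v <= 1 + 1e-12))
    expect_true(all(v >= -2 - 1e-12))
  }
  expect_error(orc_edges(g_path4, alpha = 1), "alpha")
  expect_error(orc_edge(g_path4, 1, 4), "not present")
  disc <- igraph::make_graph(edges = c(1, 2, 3, 4), directed = FALSE)
  expect_error(orc_edges(disc), "connected")
})

test_that("vertex-transitive graphs have constant edge curvature", {
  for (g in list(igraph::make_ring(5), igraph::make_ring(8),
                 igraph::make_full_graph(5))) {
    for (vals in list(orc_edges(g), frc_edges(g, "augmented"),
                      frc_edges(g, "classical")))
      expect_lt(diff(range(vals)), 1e-12)
  }
})

test_that("curvature is invariant under node relabeling", {
  g <- igraph::make_graph(edges = c(1, 2, 1, 5, 2, 3, 2, 4, 2, 5, 3, 4,
                                    3, 5, 4, 5), directed = FALSE)
  set.seed(12)
  perm <- sample(5)
  g2 <- igraph::permute(g, perm)
  el <- igraph::as_edgelist(g, names = FALSE)
  for (k in seq_len(nrow(el))) {
    u <- el[k, 1]; v <- el[k, 2]
    expect_equal(orc_edge(g2, perm[u], perm[v]), orc_edge(g, u, v),
                 tolerance = 1e-12)
    expect_equal(frc_edge(g2, perm[u], perm[v]), frc_edge(g, u, v))
  }
})

test_that("node curvature is the sum of incident edge curvatures", {
  k3 <- igraph::make_full_graph(3)
  expect_equal(node_curvature(frc_edges(k3, "classical"), k3), rep(0, 3))
  star <- igraph::make_star(6, mode = "undirected")   # center + 5 leaves
  nc <- node_curvature(frc_edges(star, "classical"), star)
  expect_equal(nc[1], 5 * (4 - 5 - 1))
  # handshake identity on arbitrary graphs
  for (g in small_graph_suite(max_n = 5)) {
    fe <- frc_edges(g, "augmented")
    expect_equal(sum(node_curvature(fe, g)), 2 * sum(fe))
  }
  expect_error(node_curvature(c(1, 2), k3), "cover")
})

test_that("average edge curvature is the plain mean", {
  k2 <- igraph::make_graph(edges = c(1, 2), directed = FALSE)
  expect_equal(average_edge_curvature(frc_edges(k2, "classical")), 2)
  expect_equal(average_edge_curvature(frc_edges(g_path4, "classical")), 2 / 3)
  k4 <- igraph::make_full_graph(4)
  expect_equal(average_edge_curvature(orc_edges(k4)), 2 / 3,
               tolerance = 1e-9)
  expect_error(average_edge_curvature(numeric(0)), "empty")
})

test_that("curvature_table assembles consistent edge and node frames", {
  g <- igraph::make_full_graph(4)
  ct <- curvature_table(g, orc = TRUE)
  expect_named(ct$edges, c("u", "v", "frc", "orc"))
  expect_equal(ct$nodes$frc_node, node_curvature(ct$edges$frc, g))
  expect_equal(sum(ct$nodes$orc_node), 2 * sum(ct$edges$orc),
               tolerance = 1e-12)
  d <- withr::local_tempdir()
  write_curvature_table(ct, file.path(d, "k4"))
  back <- read.delim(file.path(d, "k4_edges.tsv"))
  expect_equal(back$frc, ct$edges$frc)
})

test_that("the transport solver agrees with the simplex on random problems", {
  set.seed(2024)
  for (rep in 1:25) {
    m <- sample(2:5, 1); n <- sample(2:5, 1)
    mu <- runif(m); mu <- mu / sum(mu)
    mv <- runif(n); mv <- mv / sum(mv)
    cost <- matrix(sample(0:4, m * n, replace = TRUE), m, n)
    expect_equal(min_cost_transport(mu, mv, cost),
                 lp_transport_oracle(mu, mv, cost), tolerance = 1e-9)
  }
  expect_error(min_cost_transport(c(1, 1), c(1), matrix(1, 2, 1)),
               "unbalanced")
})
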