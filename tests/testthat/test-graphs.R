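test_that("ER generator produces simple graphs with the requested size", {
  g <- graph_er(80, 320, seed = 1)
  expect_equal(igraph::vcount(g), 80)
  expect_equal(igraph::ecount(g), 320)
  expect_true(igraph::is_simple(g))
  expect_equal(sum(igraph::degree(g)), 2 * 320)

  # forced extremes: the only simple graphs with these parameters
  expect_true(igraph::is_isomorphic_to(graph_er(3, 3), igraph::make_ring(3)))
  expect_equal(igraph::degree(graph_er(5, 10)), rep(4, 5))
  expect_error(graph_er(5, 11), "between 0 and")

  # reproducibility and require_connected
  expect_identical(igraph::as_edgelist(graph_er(40, 60, seed = 7)),
                   igraph::as_edgelist(graph_er(40, 60, seed = 7)))
  expect_true(igraph::is_connected(
    graph_er(30, 32, seed = 3, require_connected = TRUE)))
})

test_that("BA generator follows the complete-core attachment convention", {
  g <- graph_ba(80, 1, seed = 2)
  expect_equal(igraph::ecount(g), 79)           # a tree
  expect_true(igraph::is_connected(g))
  expect_equal(igraph::vcount(g) - 1, igraph::ecount(g))

  expect_true(igraph::is_isomorphic_to(graph_ba(4, 3),
                                       igraph::make_full_graph(4)))
  # deterministic edge count M = C(m,2) + m(N-m)
  g8 <- graph_ba(80, 8, seed = 3)
  expect_equal(igraph::ecount(g8), choose(8, 2) + 8 * 72)
  expect_true(igraph::is_simple(g8))
  # heavy-tailed degrees: hubs dominate the mean across seeds, the more so
  # the smaller the attachment parameter
  ratio <- function(m, s) {
    d <- igraph::degree(graph_ba(80, m, seed = s))
    max(d) / mean(d)
  }
  expect_true(all(vapply(1:5, function(s) ratio(8, s), numeric(1)) > 2))
  expect_true(all(vapply(1:5, function(s) ratio(2, s), numeric(1)) > 3))
  # and clearly exceed an edge-matched ER graph's maximum degree
  ba_max <- vapply(1:5, function(s) {
    max(igraph::degree(graph_ba(80, 8, seed = s)))
  }, numeric(1))
  er_max <- vapply(1:5, function(s) {
    max(igraph::degree(graph_er(80, 604, seed = s)))
  }, numeric(1))
  expect_gt(mean(ba_max), mean(er_max) + 10)
  expect_error(graph_ba(5, 5), "1 <= m < n")

  map <- ba_m_for_edges(80, 640)
  expect_equal(igraph::ecount(graph_ba(80, map$m, seed = 1)), map$m_realized)
})

test_that("layered view matches an independent all-pairs distance table", {
  g <- graph_er(80, 320, seed = 11)
  lv <- layered_view(g, 5)
  # oracle: full distance matrix from igraph (different code path: all-pairs)
  d <- igraph::distances(g)[5, ]
  for (k in seq_along(lv$layers)) {
    expect_setequal(lv$layers[[k]], which(d == k))
  }
  expect_setequal(lv$unreachable, which(is.infinite(d)))
  expect_setequal(lv$layers[[1]], as.integer(igraph::neighbors(g, 5)))
  expect_equal(lv$output_layer, lv$layers[[length(lv$layers)]])
})

test_that("layers partition reachable nodes and no edge skips a layer", {
  for (seed in 1:6) {
    g <- graph_er(40, sample(40:200, 1), seed = seed)
    lv <- layered_view(g, 1)
    all_nodes <- unlist(lv$layers)
    expect_equal(anyDuplicated(all_nodes), 0)
    expect_setequal(c(1L, all_nodes, lv$unreachable), seq_len(40))
    el <- igraph::as_edgelist(g, names = FALSE)
    dd <- lv$dist
    span <- abs(dd[el[, 1]] - dd[el[, 2]])
    expect_true(all(span[is.finite(span)] <= 1))
  }
})

test_that("trivial layered views: path end and star centre", {
  toy <- toy_graphs()
  lv <- layered_view(toy$path5$graph, 1)
  expect_equal(lv$layers, list(2L, 3L, 4L, 5L))
  expect_equal(lv$output_layer, 5L)
  lv <- layered_view(toy$star$graph, 1)
  expect_length(lv$layers, 1)
  expect_setequal(lv$layers[[1]], 2:10)
})

test_that("output node selection is uniform over the output layer", {
  g <- igraph::make_graph(edges = c(1, 2, 2, 3, 2, 4), directed = FALSE)
  lv <- layered_view(g, 1)  # output layer {3, 4}
  expect_setequal(lv$output_layer, c(3L, 4L))
  picks <- vapply(1:400, function(s) select_output_node(lv, seed = s),
                  integer(1))
  expect_true(all(picks %in% c(3L, 4L)))
  frac <- mean(picks == 3L)
  expect_gt(frac, 0.4)  # binomial(400, .5) band
  expect_lt(frac, 0.6)
  # size-1 output layer: that node
  lv2 <- layered_view(toy_graphs()$path5$graph, 1)
  expect_equal(select_output_node(lv2, seed = 1), 5L)
  # isolated input is flagged and refused
  g_iso <- igraph::make_graph(edges = c(2, 3), directed = FALSE, n = 3)
  expect_error(select_output_node(layered_view(g_iso, 1)), "empty")
})

test_that("minimax-path degree matches hand-worked examples", {
  toy <- toy_graphs()
  expect_equal(minimax_path_degree(toy$path5$graph, 1, 5), 2)
  # hub route vs chain route: the easiest path avoids the hub
  g <- igraph::make_graph(
    edges = c(1, 2, 2, 3, 1, 4, 4, 3, 4, 5, 4, 6, 4, 7), directed = FALSE)
  # input 1, output 3: via node 2 (deg 2) max = 2; via hub 4 (deg 5) max = 5
  expect_equal(igraph::degree(g, 4), 5)
  expect_equal(minimax_path_degree(g, 1, 3), 2)
  # complete graph: single edge to output of degree n-1
  k5 <- igraph::make_full_graph(5)
  expect_equal(minimax_path_degree(k5, 1, 2), 4)
  expect_error(minimax_path_degree(k5, 1, 1), "differ")
  g_iso <- igraph::make_graph(edges = c(1, 2), directed = FALSE, n = 3)
  expect_error(minimax_path_degree(g_iso, 1, 3), "unreachable")
})

test_that("bottleneck Dijkstra equals exhaustive path enumeration (N <= 9)", {
  for (seed in 1:40) {
    n <- sample(4:9, 1)
    m <- sample(n:min(14, n * (n - 1) / 2), 1)
    g <- graph_er(n, m, seed = seed)
    d <- igraph::distances(g)
    for (inp in 1:2) {
      reach <- setdiff(which(is.finite(d[inp, ])), inp)
      for (out in reach) {
        expect_equal(minimax_path_degree(g, inp, out),
                     brute_minimax(g, inp, out),
                     info = sprintf("seed %d, %d -> %d", seed, inp, out))
      }
    }
  }
})

test_that("topological predictors respect their ordering invariants", {
  toy <- toy_graphs()
  pr <- topological_predictors(toy$star$graph, 1, 2)
  expect_equal(pr$k_star, 1)     # leaves have degree 1
  expect_equal(pr$k_max1, 1)
  pr <- topological_predictors(toy$diamond$graph, 1, 5)
  expect_equal(pr$k_star, 3)     # both routes cross the degree-3 node
  g <- graph_er(80, 320, seed = 13)
  lv <- layered_view(g, 1)
  for (out in lv$output_layer) {
    pr <- topological_predictors(g, 1, out)
    expect_lte(pr$k_double_star, pr$k_star)
    expect_lte(pr$k_star, pr$k_max)
    expect_lte(pr$k_max1, pr$k_max)
  }
  # k** equals the explicit minimum over per-output-node minimax values
  pr <- topological_predictors(g, 1, lv$output_layer[1])
  per_node <- vapply(lv$output_layer, function(o) {
    minimax_path_degree(g, 1, o)
  }, integer(1))
  expect_equal(pr$k_double_star, min(per_node))
})

test_that("mean maximal degree grows with edge count in ER ensembles", {
  ms <- c(150, 640, 1500)
  mean_kmax <- vapply(ms, function(m) {
    mean(vapply(1:50, function(s) {
      max(igraph::degree(graph_er(80, m, seed = 7000 + 50 * m + s)))
    }, numeric(1)))
  }, numeric(1))
  expect_true(all(diff(mean_kmax) > 0))
})

test_that("edge-list files round-trip with 0-based ids and comments", {
  g <- graph_er(20, 40, seed = 5)
  path <- withr::local_tempfile(fileext = ".edges")
  write_edgelist(g, path)
  txt <- readLines(path)
  expect_true(startsWith(txt[1], "#"))
  ids <- scan(text = txt[-1], quiet = TRUE)
  expect_true(min(ids) >= 0 && max(ids) <= 19)  # 0-based on disk
  g2 <- read_edgelist(path, n = 20)
  expect_true(igraph::identical_graphs(
    igraph::simplify(g), igraph::simplify(g2)) ||
    isTRUE(all.equal(sort(as.vector(igraph::as_edgelist(g))),
                     sort(as.vector(igraph::as_edgelist(g2))))))
})

test_that("GraphML files round-trip", {
  g <- graph_er(15, 30, seed = 6)
  path <- withr::local_tempfile(fileext = ".graphml")
  write_graphml(g, path)
  g2 <- read_graphml(path)
  expect_equal(igraph::vcount(g2), 15)
  expect_equal(igraph::ecount(g2), 30)
  expect_equal(sort(igraph::degree(g2)), sort(igraph::degree(g)))
})
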