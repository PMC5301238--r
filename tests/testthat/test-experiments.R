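test_that("run_single reproduces hand-simulated propagation", {
  toy <- toy_graphs()
  # path graph at 1/kappa = 2: the front passes once
  expect_equal(run_single(toy$path5$graph, 1, 5, inv_kappa = 2), 1L)
  # all first-layer nodes are barriers at 1/kappa = 1
  expect_equal(run_single(toy$path5$graph, 1, 5, inv_kappa = 1), 0L)
  # trees at 1/kappa >= k_max: exactly one record, any p, any duration
  tree <- toy$tree$graph
  for (p in c(0.3, 1)) {
    expect_equal(run_single(tree, 1, 15, inv_kappa = 10, p = p, tmax = 500,
                            seed = 1), 1L)
  }
  expect_error(run_single(toy$path5$graph, 2, 2, inv_kappa = 2), "differ")
  g_iso <- igraph::make_graph(edges = c(1, 2), directed = FALSE, n = 3)
  expect_error(run_single(g_iso, 1, 3, inv_kappa = 2), "unreachable")
})

test_that("response curve shows zero plateau, amplified middle, single record", {
  g <- graph_er(80, 320, seed = 42)
  lv <- layered_view(g, 1)
  out <- select_output_node(lv, seed = 1)
  rc <- response_curve(g, 1, out, inv_kappa = 1:50, p = 0.5, tmax = 40,
                       n_runs = 30, seed = 77)
  det <- rc$deterministic
  expect_true(all(rc$runs$count >= 0 & rc$runs$count <= 40))
  expect_true(all(rc$mean$mean_count >= 0 & rc$mean$mean_count <= 40))
  # zero plateau before the onset
  expect_equal(det$count[det$inv_kappa == 1], 0L)
  # elevated middle region
  expect_gt(max(det$count), 2)
  # single-record regime at large 1/kappa (both deterministic and stochastic)
  expect_equal(det$count[det$inv_kappa == 50], 1L)
  expect_true(all(rc$runs$count[rc$runs$inv_kappa == 50] == 1L))
  # deterministic curve delimits the stochastic possibility space at the top
  expect_gte(max(det$count), max(rc$runs$count))
})

test_that("onset search matches hand-analysed graphs", {
  toy <- toy_graphs()
  kc <- find_kappa_c(toy$path5$graph, 1, 5)
  expect_equal(kc$rounded, 2L)
  expect_equal(kc$status, "ok")
  # star centre input: leaves are degree 1
  expect_equal(find_kappa_c(toy$star$graph, 1, 2)$rounded, 1L)
  # diamond: two simultaneous excitations pass the strength-2 barrier of the
  # degree-3 node, so the onset (2) undercuts the single-excitation
  # prediction k* = 3
  kd <- find_kappa_c(toy$diamond$graph, 1, 5)
  expect_equal(kd$rounded, 2L)
  expect_lt(kd$rounded, topological_predictors(toy$diamond$graph, 1, 5)$k_star)
})

test_that("onset search brackets are verified by direct simulation", {
  g <- graph_er(80, 320, seed = 19)
  lv <- layered_view(g, 2)
  out <- select_output_node(lv, seed = 3)
  kc <- find_kappa_c(g, 2, out)
  expect_equal(kc$status, "ok")
  eps <- 0.3
  expect_gte(run_single(g, 2, out, kc$value + eps, p = 1, tmax = 300), 1L)
  expect_equal(run_single(g, 2, out, max(1, kc$value - eps), p = 1,
                          tmax = 300), 0L)
})

test_that("limit-of-activity search: trees none, cyclic graphs bracketed", {
  toy <- toy_graphs()
  expect_equal(find_kappa_m(toy$tree$graph, 1, 15)$status, "none")
  expect_equal(find_kappa_m(toy$star$graph, 1, 2)$status, "none")
  g <- graph_er(80, 640, seed = 23)
  lv <- layered_view(g, 1)
  out <- select_output_node(lv, seed = 4)
  km <- find_kappa_m(g, 1, out)
  expect_equal(km$status, "ok")
  eps <- 0.3
  # below the boundary: amplification; above: single record
  expect_gte(run_single(g, 1, out, km$value - eps, p = 1, tmax = 300), 2L)
  expect_equal(run_single(g, 1, out, km$value + eps, p = 1, tmax = 300), 1L)
})

test_that("transition report is deterministic given the root seed", {
  g <- graph_er(80, 320, seed = 31)
  a <- transition_report(g, 4, seed = 123)
  b <- transition_report(g, 4, seed = 123)
  expect_identical(a, b)
  expect_s3_class(a$kappa_c, "ser_transition")
  expect_true(is.logical(unlist(a$match)))
})

test_that("scan produces per-trial rows honouring the predictor bounds", {
  tr <- scan_transitions(c(200, 700), 2, n = 40, inputs = "all",
                         targets = "kappa_c", seed = 55)
  expect_true(all(c("k_star", "inv_kappa_c_rounded") %in% names(tr)))
  ok <- !is.na(tr$inv_kappa_c_rounded)
  expect_true(any(ok))
  expect_true(all(tr$inv_kappa_c_rounded[ok] <= tr$k_star[ok]))
  expect_true(all(tr$k_double_star <= tr$k_star))
  q1 <- prediction_quality(tr, "k_star", "kappa_c")
  q2 <- prediction_quality(tr, "k_double_star", "kappa_c")
  expect_true(all(q1$quality >= 0 & q1$quality <= 100))
  # k** refines k*
  expect_true(all(q2$quality >= q1$quality))
})

test_that("prediction_quality handles perfect and excluded trials", {
  fake <- data.frame(
    m_edges = c(100, 100, 100), k_star = c(3L, 4L, 5L),
    k_double_star = c(3L, 4L, 5L), k_max = 9L, k_max1 = 9L,
    inv_kappa_c_rounded = c(3L, 4L, NA), status_c = c("ok", "ok",
                                                      "no_propagation"))
  q <- prediction_quality(fake, "k_star", "kappa_c")
  expect_equal(q$quality, 100)
  expect_equal(q$n, 2)
  expect_equal(q$n_excluded, 1)
  expect_error(prediction_quality(fake, "k_max", "kappa_m"), "lacks")
})

test_that("saturation scan finds the deterministic capacity on dense graphs", {
  lvl <- saturation_level(3, n = 80, m_edges = 640, p = 1, tmax = 300,
                          grid = 1:50, seed = 61)
  expect_equal(lvl$per_graph$max_count, rep(100L, 3))
  expect_equal(lvl$level, 100)
  expect_equal(lvl$per_graph$min_period, rep(3L, 3))
  # trees never amplify: max count 1 regardless of p
  tree_max <- vapply(c(0.5, 1), function(p) {
    run_single(igraph::make_tree(15, 2, mode = "undirected"), 1, 15,
               inv_kappa = 20, p = p, tmax = 300, seed = 2)
  }, integer(1))
  expect_equal(tree_max, c(1L, 1L))
})

test_that("stochastic saturation stays near but above the mean-field level", {
  lvl <- saturation_level(6, n = 80, m_edges = 640, p = 0.5, tmax = 300,
                          grid = 1:50, seed = 71)
  pred <- a_max(0.5, 300)  # 75
  expect_gt(lvl$mean_max, pred - 2)        # slight excess expected, not deficit
  expect_lt(lvl$mean_max, pred * 1.25)
})
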