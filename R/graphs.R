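#' Generate an Erdos-Renyi G(N, M) random graph
#'
#' Samples a simple undirected graph uniformly among all graphs with `n`
#' labelled nodes and `m` edges (no self-loops, no multi-edges). This is the
#' substrate for the excitable-dynamics experiments; the node of interest is
#' the degree sequence, since a node of degree k acts as a barrier of
#' strength `ceiling(kappa * k)`.
#'
#' @param n Number of nodes (>= 2). Nodes are labelled `1..n`.
#' @param m Number of edges, `0 <= m <= n(n-1)/2`.
#' @param seed Optional integer seed; the same seed reproduces the same graph.
#' @param require_connected If `TRUE`, resample until the graph is connected
#'   (intended for clean ensemble scans; default `FALSE`, disconnected graphs
#'   are legal and experiments operate on the input node's component).
#' @return An [igraph::igraph] object.
#' @examples
#' g <- graph_er(80, 320, seed = 1)
#' igraph::ecount(g)
#' @export
graph_er <- function(n, m, seed = NULL, require_connected = FALSE) {
  n <- as.integer(n); m <- as.integer(m)
  if (n < 2) stop("n must be >= 2")
  if (m < 0 || m > n * (n - 1) / 2) {
    stop("m must be between 0 and n(n-1)/2 = ", n * (n - 1) / 2)
  }
  with_seed_or_not(seed, {
    repeat {
      g <- igraph::sample_gnm(n, m, directed = FALSE, loops = FALSE)
      if (!require_connected || igraph::is_connected(g)) break
    }
    g
  })
}

#' Generate a Barabasi-Albert preferential-attachment graph
#'
#' Starts from a complete core of `m` nodes, then attaches the remaining
#' `n - m` nodes one at a time, each with `m` edges to distinct existing
#' nodes chosen with probability proportional to their current degree
#' (sampling without replacement). The edge count is the deterministic
#' function `choose(m, 2) + m * (n - m)` of `(n, m)`.
#'
#' @param n Number of nodes.
#' @param m Edges added per new node, `1 <= m < n`.
#' @param seed Optional integer seed.
#' @return An [igraph::igraph] object with `choose(m, 2) + m * (n - m)` edges.
#' @examples
#' g <- graph_ba(80, 8, seed = 1)
#' max(igraph::degree(g)) / mean(igraph::degree(g))  # heavy-tailed degrees
#' @export
graph_ba <- function(n, m, seed = NULL) {
  n <- as.integer(n); m <- as.integer(m)
  if (m < 1 || m >= n) stop("m must satisfy 1 <= m < n")
  with_seed_or_not(seed, {
    deg <- integer(n)
    core <- if (m == 1) cbind(integer(0), integer(0)) else t(utils::combn(m, 2))
    edges <- matrix(0L, nrow = m * (n - m) + nrow(core), ncol = 2)
    if (nrow(core) > 0) {
      edges[seq_len(nrow(core)), ] <- core
      deg[1:m] <- m - 1L
    }
    pos <- nrow(core)
    for (v in seq.int(m + 1L, n)) {
      existing <- seq_len(v - 1L)
      # degree-proportional weights; the m = 1 start has degree-0 cores, give
      # every node a +1 offset there so the first attachment is well defined
      w <- deg[existing]
      if (all(w == 0)) w <- w + 1
      targets <- sample(existing, m, prob = w)
      edges[pos + seq_len(m), ] <- cbind(v, targets)
      pos <- pos + m
      deg[targets] <- deg[targets] + 1L
      deg[v] <- deg[v] + m
    }
    igraph::graph_from_edgelist(edges, directed = FALSE)
  })
}

#' Choose the attachment parameter m approximating a target edge count
#'
#' The Barabasi-Albert construction has `M = choose(m, 2) + m * (n - m)`
#' edges; ensemble scans specified by a target edge count use the `m` whose
#' realized `M` is closest to the target. The mapping is recorded in scan
#' metadata.
#'
#' @param n Number of nodes.
#' @param m_target Desired edge count.
#' @return A list with elements `m` (attachment parameter) and `m_realized`
#'   (edge count actually produced).
#' @export
ba_m_for_edges <- function(n, m_target) {
  ms <- seq_len(n - 1L)
  realized <- choose(ms, 2) + ms * (n - ms)
  i <- which.min(abs(realized - m_target))
  list(m = ms[i], m_realized = as.integer(realized[i]))
}

#' Layered (BFS) view of a graph from an input node
#'
#' Partitions the nodes reachable from `input` by their shortest-path
#' distance to it: layer 1 holds the input node's neighbours, layer 2 its
#' second neighbours, and so on. The farthest non-empty layer is the output
#' layer, from which output nodes are drawn. By construction no edge skips a
#' layer. At low enough 1/kappa the excitation signal propagates layer-wise,
#' like a front, which is what makes this decomposition the natural frame for
#' the dynamics.
#'
#' @param graph An igraph object.
#' @param input Input node id (1-based).
#' @return An object of class `ser_layers`: a list with `input`, `layers`
#'   (list of integer vectors, index = distance), `output_layer`,
#'   `unreachable` (nodes with no path to `input`), and `dist` (per-node
#'   distance, `Inf` when unreachable).
#' @examples
#' g <- graph_er(80, 320, seed = 1)
#' lv <- layered_view(g, 1)
#' lengths(lv$layers)
#' @export
layered_view <- function(graph, input) {
  input <- as.integer(input)
  n <- igraph::vcount(graph)
  if (input < 1 || input > n) stop("input node not in graph")
  d <- as.numeric(igraph::distances(graph, v = input)[1, ])
  reach <- which(is.finite(d) & d > 0)
  layers <- list()
  if (length(reach)) {
    dmax <- max(d[reach])
    layers <- lapply(seq_len(dmax), function(k) as.integer(which(d == k)))
  }
  structure(
    list(
      input = input,
      layers = layers,
      output_layer = if (length(layers)) layers[[length(layers)]] else integer(0),
      unreachable = as.integer(which(is.infinite(d))),
      dist = d
    ),
    class = "ser_layers"
  )
}

#' @export
print.ser_layers <- function(x, ...) {
  cat("Layered view from input node", x$input, "\n")
  cat("  layers:", length(x$layers),
      " sizes:", paste(lengths(x$layers), collapse = " "), "\n")
  cat("  output layer size:", length(x$output_layer),
      " unreachable:", length(x$unreachable), "\n")
  invisible(x)
}

#' Select an output node from the output layer
#'
#' Draws one node uniformly at random from the farthest non-empty layer of a
#' [layered_view()].
#'
#' @param lv A `ser_layers` object.
#' @param seed Optional integer seed.
#' @return A node id.
#' @export
select_output_node <- function(lv, seed = NULL) {
  stopifnot(inherits(lv, "ser_layers"))
  out <- lv$output_layer
  if (!length(out)) stop("output layer is empty (isolated input node)")
  with_seed_or_not(seed, out[sample.int(length(out), 1L)])
}

# Minimax-path (widest-path / bottleneck) labels from `input` to every node:
# label(v) = min over input->v paths of the maximal degree along the path,
# excluding the input node's own degree and including v's. Modified Dijkstra
# on the running maximum; O(N^2), ample for the network sizes studied here.
minimax_labels <- function(graph, input) {
  n <- igraph::vcount(graph)
  deg <- as.numeric(igraph::degree(graph))
  adj <- igraph::as_adj_list(graph)
  lab <- rep(Inf, n)
  lab[input] <- 0          # input excited externally: its degree not counted
  done <- rep(FALSE, n)
  repeat {
    cand <- which(!done & is.finite(lab))
    if (!length(cand)) break
    u <- cand[which.min(lab[cand])]
    done[u] <- TRUE
    for (v in as.integer(adj[[u]])) {
      if (!done[v]) lab[v] <- min(lab[v], max(lab[u], deg[v]))
    }
  }
  lab
}

#' Minimax-path bottleneck degree k*
#'
#' Over all paths from the input node to the output node, the minimum of the
#' maximal node degree encountered along the path — the largest degree on the
#' "easiest" path. A single excitation fails at any node whose degree exceeds
#' 1/kappa, so k* predicts the onset 1/kappa_c of excitation propagation
#' (it is an upper bound: concurrent multiple excitations can pass stronger
#' barriers). The input node's degree is excluded (it is excited externally);
#' the output node's own degree is included (it must pass its own barrier).
#' Computed with a bottleneck variant of Dijkstra's algorithm, not by path
#' enumeration.
#'
#' @param graph An igraph object.
#' @param input,output Node ids.
#' @return The integer bottleneck degree `k*`.
#' @examples
#' g <- igraph::make_graph(~ A - B - C - D)  # path graph
#' minimax_path_degree(g, 1, 4)              # internal degrees 2 -> k* = 2
#' @export
minimax_path_degree <- function(graph, input, output) {
  input <- as.integer(input); output <- as.integer(output)
  if (input == output) stop("input and output must differ")
  lab <- minimax_labels(graph, input)
  if (!is.finite(lab[output])) stop("output node unreachable from input node")
  as.integer(lab[output])
}

#' Topological predictors of the two transition points
#'
#' Computes, for a (graph, input, output) triple, the four degree-based
#' predictors of the response-curve transitions:
#' * `k_star` — minimax-path degree to the given output node; predicts the
#'   onset of propagation 1/kappa_c.
#' * `k_double_star` — minimum of `k_star` over every node of the output
#'   layer (the easiest path to the output layer); refines `k_star`.
#' * `k_max` — maximal degree in the input node's connected component;
#'   predicts the limit of self-sustained activity 1/kappa_m in sparse graphs.
#' * `k_max1` — maximal degree in the first layer (the input node's
#'   neighbours); predicts 1/kappa_m in dense graphs, where the first
#'   susceptible "hole" appears in the first layer.
#'
#' @param graph An igraph object.
#' @param input,output Node ids; `output` must be reachable from `input`.
#' @return An object of class `ser_predictors`: a list with integer fields
#'   `k_star`, `k_double_star`, `k_max`, `k_max1`.
#' @examples
#' g <- graph_er(80, 320, seed = 1)
#' lv <- layered_view(g, 1)
#' out <- select_output_node(lv, seed = 2)
#' topological_predictors(g, 1, out)
#' @export
topological_predictors <- function(graph, input, output) {
  input <- as.integer(input); output <- as.integer(output)
  lv <- layered_view(graph, input)
  if (!length(lv$output_layer)) stop("input node is isolated")
  lab <- minimax_labels(graph, input)
  if (!is.finite(lab[output])) stop("output node unreachable from input node")
  deg <- igraph::degree(graph)
  comp <- setdiff(which(is.finite(lv$dist)), integer(0))
  structure(
    list(
      k_star = as.integer(lab[output]),
      k_double_star = as.integer(min(lab[lv$output_layer])),
      k_max = as.integer(max(deg[comp])),
      k_max1 = as.integer(max(deg[lv$layers[[1]]]))
    ),
    class = "ser_predictors"
  )
}

#' @export
print.ser_predictors <- function(x, ...) {
  cat(sprintf("k* = %d  k** = %d  k_max = %d  k_max,1 = %d\n",
              x$k_star, x$k_double_star, x$k_max, x$k_max1))
  invisible(x)
}

#' Read and write plain-text edge lists
#'
#' One edge per line, two whitespace-separated integer node ids, `#` starts a
#' comment. Files use 0-based node ids (a common convention for edge-list
#' interchange); the in-memory graphs use igraph's 1-based ids, converted on
#' the way in and out.
#'
#' @param path File path.
#' @param n Optional node count (to keep trailing isolated nodes); defaults
#'   to the largest id seen.
#' @param graph An igraph object.
#' @return `read_edgelist()` returns an igraph object; `write_edgelist()`
#'   returns `path` invisibly.
#' @export
read_edgelist <- function(path, n = NULL) {
  tab <- utils::read.table(path, comment.char = "#",
                           col.names = c("from", "to"),
                           colClasses = "integer")
  el <- as.matrix(tab) + 1L
  nv <- if (is.null(n)) max(el, 1L) else as.integer(n)
  igraph::graph_from_edgelist(el, directed = FALSE) |>
    igraph::add_vertices(max(0L, nv - max(el, 0L)))
}

#' @rdname read_edgelist
#' @export
write_edgelist <- function(graph, path) {
  el <- igraph::as_edgelist(graph, names = FALSE) - 1L
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    sprintf("# undirected simple graph: %d nodes, %d edges (0-based ids)",
            igraph::vcount(graph), igraph::ecount(graph)),
    sprintf("%d %d", el[, 1], el[, 2])
  ), con)
  invisible(path)
}

#' Read and write GraphML
#'
#' Thin wrappers over igraph's GraphML support, for interoperability with
#' other network tools.
#'
#' @param path File path.
#' @param graph An igraph object.
#' @return `read_graphml()` returns an igraph object.
#' @export
read_graphml <- function(path) igraph::read_graph(path, format = "graphml")

#' @rdname read_graphml
#' @export
write_graphml <- function(graph, path) {
  igraph::write_graph(graph, path, format = "graphml")
  invisible(path)
}
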