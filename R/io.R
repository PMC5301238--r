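.spec_defaults <- list(
  model = NULL, n_nodes = NULL, m_edges = NULL, graph_file = NULL,
  input = NULL, output = NULL,
  inv_kappa = 1:50, p = 1, tmax = 300, n_runs = 30,
  seed = NULL, require_connected = FALSE
)

#' Load an experiment configuration
#'
#' Reads a YAML configuration into a fully resolved experiment
#' specification, filling documented defaults (`tmax = 300`, grid
#' `inv_kappa = 1..50`, `n_runs = 30`, `p = 1`). Unknown keys are rejected
#' by name. A configuration names its graph either by generator parameters
#' (`model: er|ba` with `n_nodes` and `m_edges`) or by `graph_file` (edge
#' list or GraphML by extension); `input`/`output` may be explicit node ids
#' or absent for random selection. The size keys are spelled `n_nodes` /
#' `m_edges` rather than bare `n` / `m` because YAML 1.1 resolves a bare
#' `n` key to a boolean.
#'
#' @param path Path to a YAML file (or a list, already parsed).
#' @return A list of class `ser_spec` with the resolved fields.
#' @export
load_config <- function(path) {
  cfg <- if (is.list(path)) path else yaml::read_yaml(path)
  if (is.null(cfg)) cfg <- list()
  unknown <- setdiff(names(cfg), names(.spec_defaults))
  if (length(unknown)) {
    stop("unknown configuration key(s): ", paste(unknown, collapse = ", "))
  }
  spec <- utils::modifyList(.spec_defaults, cfg, keep.null = TRUE)
  if (is.null(spec$graph_file)) {
    if (is.null(spec$model) || is.null(spec$n_nodes) ||
        is.null(spec$m_edges)) {
      stop("configuration must set either graph_file or model, ",
           "n_nodes and m_edges")
    }
    spec$model <- match.arg(spec$model, c("er", "ba"))
  }
  if (any(spec$inv_kappa < 1)) stop("inv_kappa values must be >= 1")
  if (spec$tmax < 1) stop("tmax must be >= 1")
  if (spec$n_runs < 1) stop("n_runs must be >= 1")
  if (spec$p <= 0 || spec$p > 1) stop("p must be in (0, 1]")
  structure(spec, class = "ser_spec")
}

#' Normalize and serialize a configuration
#'
#' `dump_config()` writes the resolved specification back to YAML;
#' `load_config(dump_config(x))` is idempotent.
#'
#' @param spec A `ser_spec` from [load_config()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
dump_config <- function(spec, path) {
  stopifnot(inherits(spec, "ser_spec"))
  yaml::write_yaml(Filter(Negate(is.null), unclass(spec)), path)
  invisible(path)
}

#' Resolve the graph named by a configuration
#'
#' @param spec A `ser_spec`.
#' @param seed Optional seed overriding `spec$seed` for generation.
#' @return An igraph object.
#' @export
spec_graph <- function(spec, seed = NULL) {
  stopifnot(inherits(spec, "ser_spec"))
  if (!is.null(spec$graph_file)) {
    if (grepl("\\.graphml$", spec$graph_file)) {
      return(read_graphml(spec$graph_file))
    }
    return(read_edgelist(spec$graph_file))
  }
  seed <- if (is.null(seed)) spec$seed else seed
  if (spec$model == "er") {
    graph_er(spec$n_nodes, spec$m_edges, seed = seed,
             require_connected = isTRUE(spec$require_connected))
  } else {
    graph_ba(spec$n_nodes, ba_m_for_edges(spec$n_nodes, spec$m_edges)$m,
             seed = seed)
  }
}

#' Run manifest for reproducibility
#'
#' Collects everything needed to reproduce a run: the configuration echo,
#' the root seed and the derived child seeds, the package version and a
#' timestamp, plus the graph provenance (generator parameters, or file path
#' and content hash). Deterministic (`p = 1`) results rerun bit-exactly
#' from a manifest.
#'
#' @param spec A `ser_spec`.
#' @param seed Root seed used.
#' @param child_seeds Derived child seeds (from [derive_seeds()]).
#' @return A list of class `ser_manifest`, serializable with
#'   [jsonlite::write_json()].
#' @export
make_manifest <- function(spec, seed = NULL, child_seeds = NULL) {
  prov <- if (!is.null(spec$graph_file)) {
    list(file = spec$graph_file,
         md5 = unname(tools::md5sum(spec$graph_file)))
  } else {
    list(model = spec$model, n_nodes = spec$n_nodes, m_edges = spec$m_edges)
  }
  structure(
    list(
      config = Filter(Negate(is.null), unclass(spec)),
      seed = seed,
      child_seeds = child_seeds,
      graph = prov,
      package_version = as.character(utils::packageVersion("sergraph")),
      timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")
    ),
    class = "ser_manifest"
  )
}

#' Deterministic library of test graphs
#'
#' A fixed set of micro-graphs (plus three seeded random graphs) used
#' throughout the test suite, each bundled with its canonical input and
#' output node:
#' * `path5` — path of 5 nodes, input at one end (internal degrees 2).
#' * `star` — star of 9 leaves, input at the centre (a tree: no
#'   amplification ever).
#' * `triangle` — the 3-cycle.
#' * `diamond` — input joined to two degree-2 nodes that both feed a
#'   degree-3 node in front of the output: the minimal graph where two
#'   simultaneous excitations pass a strength-2 barrier, so the measured
#'   onset (2) beats the single-excitation prediction k* = 3.
#' * `tree` — a binary tree of 15 nodes.
#' * `er_dense` — ER graph, N = 80, M = 640, fixed seed.
#' * `er_sparse` — ER graph, N = 80, M = 150, fixed seed.
#' * `ba` — Barabasi-Albert graph, N = 80, m = 8, fixed seed.
#'
#' @return A named list; each element is a list with `graph`, `input`,
#'   `output` (`NULL` for the random graphs, where the output is drawn from
#'   the output layer at test time).
#' @export
fixture_graphs <- function() {
  path5 <- igraph::make_graph(edges = c(1, 2, 2, 3, 3, 4, 4, 5),
                              directed = FALSE)
  star <- igraph::make_star(10, mode = "undirected", center = 1)
  triangle <- igraph::make_ring(3)
  diamond <- igraph::make_graph(
    edges = c(1, 2, 1, 3, 2, 4, 3, 4, 4, 5), directed = FALSE)
  tree <- igraph::make_tree(15, children = 2, mode = "undirected")
  list(
    path5 = list(graph = path5, input = 1L, output = 5L),
    star = list(graph = star, input = 1L, output = 2L),
    triangle = list(graph = triangle, input = 1L, output = 3L),
    diamond = list(graph = diamond, input = 1L, output = 5L),
    tree = list(graph = tree, input = 1L, output = 15L),
    er_dense = list(graph = graph_er(80, 640, seed = 20170210L),
                    input = 1L, output = NULL),
    er_sparse = list(graph = graph_er(80, 150, seed = 20170211L),
                     input = 1L, output = NULL),
    ba = list(graph = graph_ba(80, 8, seed = 20170212L),
              input = 1L, output = NULL)
  )
}

#' Write accumulated excitation counts as JSON
#'
#' @param run A `ser_run`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_counts_json <- function(run, path) {
  jsonlite::write_json(
    as.list(setNames(run$counts, seq_along(run$counts))),
    path, auto_unbox = TRUE)
  invisible(path)
}
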