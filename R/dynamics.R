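#' Barrier strength of a node
#'
#' A susceptible node of degree `k` switches to the excited state when at
#' least `kappa * k` of its neighbours are excited. The smallest integer
#' greater than or equal to `kappa * k` is therefore the number of
#' simultaneously excited neighbours the node requires — the strength with
#' which it acts as a barrier to propagation. Nodes of degree 0 return 0 and
#' can never be excited by neighbours.
#'
#' The ceiling is taken with a small guard against floating-point noise so
#' that exactly attainable products (for example `k = 5`, `kappa = 0.2`,
#' `kappa * k = 1`) land on the correct integer.
#'
#' @param k Node degree(s), non-negative integer(s).
#' @param kappa Relative excitation threshold in (0, 1].
#' @return Integer barrier strength(s), vectorised over `k`.
#' @examples
#' barrier_strength(4, 0.3)  # ceiling(1.2) = 2
#' barrier_strength(5, 0.2)  # exactly 1: one excited neighbour suffices
#' @export
barrier_strength <- function(k, kappa) {
  stopifnot(all(k >= 0), kappa > 0, kappa <= 1)
  as.integer(ceiling(k * kappa - 1e-9))
}

#' Build an initial SER state vector
#'
#' All nodes susceptible except the listed ones, which start excited. The
#' standard numerical experiment injects a single excitation at the input
#' node.
#'
#' @param n Number of nodes.
#' @param excited Node ids starting in state E.
#' @return An integer state vector (see [encode_states()]).
#' @export
ser_initial_state <- function(n, excited = integer(0)) {
  s <- rep(SER_S, n)
  s[as.integer(excited)] <- SER_E
  s
}

# 0-based adjacency lists handed to the C++ core.
adj_list0 <- function(graph) {
  lapply(igraph::as_adj_list(graph), function(v) as.integer(v) - 1L)
}

#' One synchronous SER update step (reference implementation)
#'
#' Applies the update rules once, computing every transition from the
#' time-`t` state (double buffering): `S -> E` iff at least `kappa * k_i`
#' neighbours are excited, `E -> R` always, `R -> S` with probability `p`.
#' There are no spontaneous excitations. This vectorised R stepper is the
#' readable reference for the compiled core used by [ser_run()]; the two are
#' tested to agree.
#'
#' @param graph An igraph object.
#' @param state Integer state vector (see [encode_states()]).
#' @param kappa Relative excitation threshold in (0, 1].
#' @param p Recovery probability in (0, 1].
#' @return The state vector after one step.
#' @examples
#' g <- igraph::make_ring(3)
#' s <- ser_initial_state(3, excited = 1)
#' decode_states(ser_step(g, s, kappa = 0.3, p = 1))
#' @export
ser_step <- function(graph, state, kappa, p = 1) {
  stopifnot(length(state) == igraph::vcount(graph),
            kappa > 0, kappa <= 1, p > 0, p <= 1)
  deg <- igraph::degree(graph)
  adj <- igraph::as_adj_list(graph)
  excited <- state == SER_E
  n_exc <- vapply(adj, function(nb) sum(excited[as.integer(nb)]), numeric(1))
  need <- barrier_strength(deg, kappa)
  nxt <- state
  nxt[state == SER_S & deg > 0 & n_exc >= need] <- SER_E
  nxt[state == SER_E] <- SER_R
  rec <- state == SER_R
  if (any(rec)) {
    if (p >= 1) {
      nxt[rec] <- SER_S
    } else {
      nxt[rec] <- ifelse(stats::runif(sum(rec)) < p, SER_S, SER_R)
    }
  }
  nxt
}

#' Run the SER dynamics for T steps
#'
#' Simulates the three-state excitable automaton with synchronous updates on
#' `graph`, starting from `init`, and accumulates per-node excitation counts
#' (the number of steps in `[1, T]` a node spends in state E; one excitation
#' lasts exactly one step, so this counts excitations). Once no node is
#' excited the activity is extinct — without spontaneous excitations it can
#' never restart — and the run exits early with final counts.
#'
#' For `p = 1` the dynamics is deterministic: no random numbers are drawn
#' and the trajectory is bit-reproducible regardless of any seed.
#'
#' @param graph An igraph object.
#' @param init Integer state vector at t = 0 (see [ser_initial_state()]).
#' @param kappa Relative excitation threshold in (0, 1].
#' @param p Recovery probability in (0, 1].
#' @param tmax Number of update steps T (>= 1).
#' @param seed Optional integer seed for the stochastic recovery.
#' @param record_states If `TRUE`, also return the full `(T+1) x N` state
#'   matrix (memory opt-in; early exit is disabled so recorded refractory
#'   durations stay exact).
#' @param watch Optional node id whose excitation times are recorded.
#' @param stop_count If > 0 and `watch` is set, stop as soon as the watched
#'   node has accumulated this many excitations (used by the transition
#'   searches, where only the indicator matters).
#' @return A list of class `ser_run` with `counts` (per-node excitation
#'   counts), `extinct_at` (first step with no excited node, `NA` if activity
#'   survived to `T`), `steps` (last step simulated), `watch_times`
#'   (excitation times of `watch`), and optionally `states`.
#' @examples
#' g <- igraph::make_graph(~ A - B - C - D)
#' r <- ser_run(g, ser_initial_state(4, excited = 1), kappa = 0.5, tmax = 10)
#' r$counts  # the front passes each node exactly once
#' @export
ser_run <- function(graph, init, kappa, p = 1, tmax = 300, seed = NULL,
                    record_states = FALSE, watch = NULL, stop_count = 0) {
  stopifnot(tmax >= 1, kappa > 0, kappa <= 1, p > 0, p <= 1,
            length(init) == igraph::vcount(graph))
  need <- barrier_strength(igraph::degree(graph), kappa)
  need[need < 1L] <- 1L  # k = 0 nodes are inert via their empty adjacency
  res <- with_seed_or_not(seed, ser_run_cpp(
    adj_list0(graph), need, as.integer(init), as.integer(tmax), p,
    record_states, if (is.null(watch)) -1L else as.integer(watch) - 1L,
    as.integer(stop_count)
  ))
  res$kappa <- kappa
  res$p <- p
  res$tmax <- as.integer(tmax)
  class(res) <- "ser_run"
  res
}

#' @export
print.ser_run <- function(x, ...) {
  cat(sprintf(
    "SER run: kappa = %.4g, p = %g, T = %d; total excitations = %d, %s\n",
    x$kappa, x$p, x$tmax, sum(x$counts),
    if (is.na(x$extinct_at)) "activity survived"
    else paste0("extinct at t = ", x$extinct_at)))
  invisible(x)
}

#' Export a recorded trajectory as a tidy table
#'
#' @param run A `ser_run` produced with `record_states = TRUE`.
#' @return A data.frame with columns `t`, `node`, `state` (one row per node
#'   and time step), suitable for CSV export.
#' @export
trajectory_table <- function(run) {
  if (is.null(run$states)) stop("run was not recorded with record_states = TRUE")
  st <- run$states
  data.frame(
    t = rep(seq_len(nrow(st)) - 1L, times = ncol(st)),
    node = rep(seq_len(ncol(st)), each = nrow(st)),
    state = decode_states(as.vector(st))
  )
}

#' Pooled refractory durations of a recorded trajectory
#'
#' Extracts every completed refractory episode (a maximal run of consecutive
#' R states followed by recovery to S) from a recorded trajectory. Episodes
#' still refractory at the end of the run are censored and dropped. Under
#' the model the durations are geometrically distributed with mean `1/p`.
#'
#' @param run A `ser_run` produced with `record_states = TRUE`.
#' @return An integer vector of refractory durations (in steps).
#' @export
refractory_durations <- function(run) {
  if (is.null(run$states)) stop("run was not recorded with record_states = TRUE")
  st <- run$states
  durs <- integer(0)
  for (i in seq_len(ncol(st))) {
    x <- st[, i]
    r <- rle(x)
    ends <- cumsum(r$lengths)
    for (j in seq_along(r$values)) {
      if (r$values[j] == SER_R && ends[j] < length(x)) {
        durs <- c(durs, r$lengths[j])
      }
    }
  }
  durs
}
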