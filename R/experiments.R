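#' Single-excitation propagation experiment
#'
#' The elementary numerical experiment: all nodes start susceptible, the
#' input node receives one excitation at t = 0, the dynamics runs for `tmax`
#' steps, and the excitations accumulated at the output node are returned.
#'
#' @param graph An igraph object.
#' @param input,output Distinct node ids; `output` must be reachable from
#'   `input`.
#' @param inv_kappa Control parameter 1/kappa (>= 1): the maximal degree a
#'   node can have and still be excited by a single excited neighbour.
#' @param p Recovery probability in (0, 1].
#' @param tmax Recording duration T.
#' @param seed Optional integer seed (ignored by the dynamics when `p = 1`).
#' @param stop_count If > 0, stop once the output node has accumulated this
#'   many excitations (the count returned is then censored at `stop_count`;
#'   used by the transition searches).
#' @param detail If `TRUE` return a list with `count`, `times` (output
#'   excitation times) and `extinct_at` instead of the bare count.
#' @return The accumulated output excitation count (integer), or a list when
#'   `detail = TRUE`.
#' @examples
#' g <- igraph::make_graph(~ A - B - C - D)
#' run_single(g, 1, 4, inv_kappa = 2)  # the front passes once
#' @export
run_single <- function(graph, input, output, inv_kappa, p = 1, tmax = 300,
                       seed = NULL, stop_count = 0, detail = FALSE) {
  input <- as.integer(input); output <- as.integer(output)
  if (input == output) stop("input and output must differ")
  if (inv_kappa < 1) stop("inv_kappa must be >= 1")
  if (!is.finite(igraph::distances(graph, v = input, to = output)[1, 1])) {
    stop("output node unreachable from input node")
  }
  init <- ser_initial_state(igraph::vcount(graph), excited = input)
  r <- ser_run(graph, init, kappa = 1 / inv_kappa, p = p, tmax = tmax,
               seed = seed, watch = output, stop_count = stop_count)
  if (detail) {
    list(count = r$counts[output], times = r$watch_times,
         extinct_at = r$extinct_at)
  } else {
    r$counts[output]
  }
}

#' Response curve: output excitations versus 1/kappa
#'
#' Sweeps the control parameter 1/kappa over a grid and records, for each
#' grid value, the accumulated output excitations of `n_runs` stochastic
#' repetitions plus one deterministic (`p = 1`) run. The curve displays the
#' three generic features of the model: the onset of propagation (point A,
#' 1/kappa_c), the limit of self-sustained activity (point B, 1/kappa_m),
#' and the saturated activity level between them (level C).
#'
#' @inheritParams run_single
#' @param inv_kappa Numeric vector of grid values (>= 1).
#' @param n_runs Number of stochastic repetitions per grid value.
#' @param seed Optional root seed; child seeds are derived per grid value.
#' @return An object of class `ser_response_curve`: a list with `runs`
#'   (data.frame: `inv_kappa`, `run`, `count`), `deterministic` (data.frame:
#'   `inv_kappa`, `count`), `mean` (data.frame: `inv_kappa`, `mean_count`),
#'   and the experiment parameters.
#' @export
response_curve <- function(graph, input, output, inv_kappa = 1:50, p = 0.5,
                           tmax = 300, n_runs = 30, seed = NULL) {
  stopifnot(all(inv_kappa >= 1), n_runs >= 1)
  seeds <- derive_seeds(seed, length(inv_kappa))
  runs <- do.call(rbind, lapply(seq_along(inv_kappa), function(i) {
    rs <- derive_seeds(if (is.null(seeds)) NULL else seeds[i], n_runs)
    counts <- vapply(seq_len(n_runs), function(r) {
      run_single(graph, input, output, inv_kappa[i], p = p, tmax = tmax,
                 seed = if (is.null(rs)) NULL else rs[r])
    }, integer(1))
    data.frame(inv_kappa = inv_kappa[i], run = seq_len(n_runs), count = counts)
  }))
  det <- data.frame(
    inv_kappa = inv_kappa,
    count = vapply(inv_kappa, function(x) {
      run_single(graph, input, output, x, p = 1, tmax = tmax)
    }, integer(1))
  )
  mean_df <- stats::aggregate(count ~ inv_kappa, runs, mean)
  names(mean_df)[2] <- "mean_count"
  structure(
    list(runs = runs, deterministic = det, mean = mean_df,
         p = p, tmax = tmax, n_runs = n_runs,
         input = input, output = output),
    class = "ser_response_curve"
  )
}

#' @export
print.ser_response_curve <- function(x, ...) {
  cat(sprintf(
    "Response curve: input %d -> output %d, p = %g, T = %d, %d runs\n",
    x$input, x$output, x$p, x$tmax, x$n_runs))
  print(utils::head(merge(x$mean, x$deterministic), 10))
  invisible(x)
}

# round-half-up; transition boundaries sit at rationals k/j, and the final
# bisection bracket is narrower than the rounding granularity, so the
# half-way tie never arises in practice — half-up just makes it defined.
round_nearest <- function(x) floor(x + 0.5)

# Indicator evaluator for the transition searches: TRUE when any of n_runs
# repetitions accumulates >= threshold output excitations. For p = 1 a
# single deterministic run decides. The adjacency structure is converted
# once up front; a search evaluates the indicator ~10 times on the same
# graph and the conversion would otherwise dominate ensemble scans.
make_indicator <- function(graph, input, output, p, tmax, n_runs, threshold,
                           seed) {
  adj0 <- adj_list0(graph)
  deg <- as.integer(igraph::degree(graph))
  n <- igraph::vcount(graph)
  input <- as.integer(input); output <- as.integer(output)
  init <- ser_initial_state(n, excited = input)
  n_eval <- 0L
  function(x) {
    n_eval <<- n_eval + 1L
    need <- pmax(1L, barrier_strength(deg, 1 / x))
    runs <- if (p >= 1) 1L else n_runs
    rs <- derive_seeds(bump_seed(seed, n_eval), runs)
    for (r in seq_len(runs)) {
      res <- with_seed_or_not(
        if (is.null(rs)) NULL else rs[r],
        ser_run_cpp(adj0, need, init, as.integer(tmax), p, FALSE,
                    output - 1L, as.integer(threshold)))
      if (res$counts[output] >= threshold) return(TRUE)
    }
    FALSE
  }
}

#' Measure the onset of excitation propagation (point A)
#'
#' Finds the smallest 1/kappa at which a single excitation injected at the
#' input node reaches the output node, by bisection on 1/kappa in `[1, N]`.
#' The propagation indicator is assumed monotone in 1/kappa; the final
#' bracket endpoints are re-verified by direct simulation, and on a
#' violation the search falls back to a linear scan over the integer grid
#' (with a warning). The result is also rounded to the nearest integer for
#' comparison with the topological predictors `k*` and `k**`.
#'
#' The transition point does not depend on the recovery probability, so the
#' default `p = 1` (deterministic dynamics) makes the search reliable; for
#' `p < 1` the indicator is "any of `n_runs` repetitions propagates".
#'
#' @inheritParams run_single
#' @param n_runs Stochastic repetitions per indicator evaluation (`p < 1`).
#' @param resolution Bisection stops once the bracket is narrower than this.
#' @return A list of class `ser_transition` with `value` (the bracket
#'   midpoint), `rounded`, and `status` (`"ok"`, `"no_propagation"`, or
#'   `"linear_scan"` when the monotonicity fallback fired).
#' @export
find_kappa_c <- function(graph, input, output, p = 1, tmax = 300, n_runs = 30,
                         resolution = 0.25, seed = NULL) {
  n <- igraph::vcount(graph)
  f <- make_indicator(graph, input, output, p, tmax, n_runs, 1L, seed)
  if (!f(n)) {
    return(structure(list(value = NA_real_, rounded = NA_integer_,
                          status = "no_propagation"),
                     class = "ser_transition"))
  }
  if (f(1)) {
    return(structure(list(value = 1, rounded = 1L, status = "ok"),
                     class = "ser_transition"))
  }
  lo <- 1; hi <- n
  while (hi - lo >= resolution) {
    mid <- (lo + hi) / 2
    if (f(mid)) hi <- mid else lo <- mid
  }
  status <- "ok"
  if (!f(hi) || f(lo)) {  # monotonicity violated: well-defined fallback
    warning("propagation indicator not monotone; falling back to linear scan")
    status <- "linear_scan"
    hit <- which(vapply(seq_len(n), f, logical(1)))[1]
    return(structure(list(value = as.numeric(hit), rounded = as.integer(hit),
                          status = status),
                     class = "ser_transition"))
  }
  value <- (lo + hi) / 2
  structure(list(value = value, rounded = as.integer(round_nearest(value)),
                 status = status),
            class = "ser_transition")
}

#' Measure the limit of self-sustained activity (point B)
#'
#' Finds the largest 1/kappa at which the output node records more than one
#' excitation within `tmax` steps. Above this point every node passes a
#' single excitation, the signal crosses the layers once as a coherent front
#' (each excited layer shadowed by a refractory one), and the output node
#' records exactly one excitation however long the experiment runs;
#' amplification below the point requires reentrant excitation of
#' topological cycles. Components without cycles therefore return the
#' sentinel status `"none"` immediately.
#'
#' The search brackets the amplification indicator (any run with >= 2 output
#' excitations) between a value where it holds — found by probing upward
#' from the measured onset on the integer grid — and `N`, then bisects, with
#' the same endpoint verification and linear-scan fallback as
#' [find_kappa_c()].
#'
#' @inheritParams find_kappa_c
#' @param onset Optional `ser_transition` from [find_kappa_c()] for the same
#'   triple (computed if missing).
#' @return A list of class `ser_transition` with `value`, `rounded`, and
#'   `status` (`"ok"`, `"none"` when no amplification exists anywhere in the
#'   range, `"no_propagation"`, or `"linear_scan"`).
#' @export
find_kappa_m <- function(graph, input, output, p = 1, tmax = 300, n_runs = 30,
                         resolution = 0.25, seed = NULL, onset = NULL) {
  n <- igraph::vcount(graph)
  none <- structure(list(value = NA_real_, rounded = NA_integer_,
                         status = "none"), class = "ser_transition")
  if (is.null(onset)) {
    onset <- find_kappa_c(graph, input, output, p = p, tmax = tmax,
                          n_runs = n_runs, resolution = resolution,
                          seed = bump_seed(seed, 1000))
  }
  if (onset$status == "no_propagation") {
    return(structure(list(value = NA_real_, rounded = NA_integer_,
                          status = "no_propagation"),
                     class = "ser_transition"))
  }
  # no cycles in the input's component => no reentry => never more than one
  # output record
  comp <- igraph::subcomponent(graph, input)
  sub <- igraph::induced_subgraph(graph, comp)
  if (igraph::ecount(sub) < igraph::vcount(sub)) return(none)

  g2 <- make_indicator(graph, input, output, p, tmax, n_runs, 2L,
                       bump_seed(seed, 2000))
  lo <- NA_real_
  for (x in unique(c(onset$value, seq(ceiling(onset$value), n)))) {
    if (g2(x)) { lo <- x; break }
  }
  if (is.na(lo)) return(none)
  if (g2(n)) {
    return(structure(list(value = as.numeric(n), rounded = as.integer(n),
                          status = "at_max"), class = "ser_transition"))
  }
  hi <- n
  while (hi - lo >= resolution) {
    mid <- (lo + hi) / 2
    if (g2(mid)) lo <- mid else hi <- mid
  }
  status <- "ok"
  if (!g2(lo) || g2(hi)) {
    warning("amplification indicator not monotone; falling back to linear scan")
    status <- "linear_scan"
    hits <- which(vapply(seq_len(n), g2, logical(1)))
    if (!length(hits)) return(none)
    hit <- hits[length(hits)]
    return(structure(list(value = as.numeric(hit), rounded = as.integer(hit),
                          status = status), class = "ser_transition"))
  }
  value <- (lo + hi) / 2
  structure(list(value = value, rounded = as.integer(round_nearest(value)),
                 status = status),
            class = "ser_transition")
}

#' @export
print.ser_transition <- function(x, ...) {
  if (is.na(x$value)) {
    cat("transition:", x$status, "\n")
  } else {
    cat(sprintf("transition at 1/kappa = %.3f (rounded %d, status %s)\n",
                x$value, x$rounded, x$status))
  }
  invisible(x)
}

#' Measure both transition points and compare with the predictors
#'
#' For one (graph, input, output) triple: computes the four topological
#' predictors, measures 1/kappa_c and 1/kappa_m by binary search under the
#' deterministic dynamics, and reports whether each predictor matches the
#' rounded measurement.
#'
#' @inheritParams find_kappa_c
#' @param output Output node id, or `NULL` to draw one at random from the
#'   output layer (using a child of `seed`).
#' @return An object of class `ser_transition_report`: a list with `input`,
#'   `output`, `predictors`, `kappa_c`, `kappa_m` (both `ser_transition`),
#'   `disconnected` flag, and logical `match` flags (`k_star`,
#'   `k_double_star` against rounded 1/kappa_c; `k_max`, `k_max1` against
#'   rounded 1/kappa_m).
#' @export
transition_report <- function(graph, input, output = NULL, p = 1, tmax = 300,
                              n_runs = 30, seed = NULL) {
  input <- as.integer(input)
  lv <- layered_view(graph, input)
  if (!length(lv$output_layer)) stop("input node is isolated")
  ch <- derive_seeds(seed, 3)
  if (is.null(output)) {
    output <- select_output_node(lv, seed = if (is.null(ch)) NULL else ch[1])
  }
  pred <- topological_predictors(graph, input, output)
  kc <- find_kappa_c(graph, input, output, p = p, tmax = tmax, n_runs = n_runs,
                     seed = if (is.null(ch)) NULL else ch[2])
  km <- find_kappa_m(graph, input, output, p = p, tmax = tmax, n_runs = n_runs,
                     seed = if (is.null(ch)) NULL else ch[3], onset = kc)
  structure(
    list(
      input = input, output = as.integer(output), predictors = pred,
      kappa_c = kc, kappa_m = km,
      disconnected = length(lv$unreachable) > 0,
      match = list(
        k_star = isTRUE(kc$rounded == pred$k_star),
        k_double_star = isTRUE(kc$rounded == pred$k_double_star),
        k_max = isTRUE(km$rounded == pred$k_max),
        k_max1 = isTRUE(km$rounded == pred$k_max1)
      )
    ),
    class = "ser_transition_report"
  )
}

#' @export
print.ser_transition_report <- function(x, ...) {
  cat(sprintf("Transition report: input %d -> output %d%s\n", x$input,
              x$output, if (x$disconnected) " (graph disconnected)" else ""))
  print(x$predictors)
  cat("  onset 1/kappa_c: "); print(x$kappa_c)
  cat("  limit 1/kappa_m: "); print(x$kappa_m)
  cat("  matches:", paste(names(x$match), unlist(x$match), sep = "=",
                          collapse = "  "), "\n")
  invisible(x)
}

#' Ensemble scan of transition measurements
#'
#' Generates an ensemble of random graphs over a grid of edge counts,
#' measures the transition points for each (graph, input) trial under the
#' deterministic dynamics, and tabulates them together with the topological
#' predictors — the raw material for prediction-quality curves.
#'
#' @param m_values Integer vector of edge counts M to scan.
#' @param n_realizations Graph realizations per M.
#' @param n Nodes per graph.
#' @param model `"er"` or `"ba"` (for `"ba"` the attachment parameter is
#'   chosen with [ba_m_for_edges()] to approximate each target M).
#' @param inputs `"all"` (every node of every graph is used as an input
#'   node) or `"random"` (one random input per graph).
#' @param targets Which transitions to measure (`"kappa_c"`, `"kappa_m"`).
#' @param p,tmax,n_runs Passed to the transition searches.
#' @param compute_pm If `TRUE`, add the mean-field multiple-excitation
#'   probability `p_m` of each trial's graph, evaluated at
#'   `kappa = 1/k_star` with recovery probability `pm_p`.
#' @param pm_p Recovery probability for the `p_m` evaluation.
#' @param seed Root seed; every graph, node choice and search derives its
#'   own child seed from it.
#' @return A data.frame with one row per (graph, input) trial: `m_edges`,
#'   `m_realized`, `graph_id`, `input`, `output`, `disconnected`,
#'   `k_star`, `k_double_star`, `k_max`, `k_max1`, `inv_kappa_c`,
#'   `inv_kappa_c_rounded`, `status_c`, and (when requested) `inv_kappa_m`,
#'   `inv_kappa_m_rounded`, `status_m`, `p_m`.
#' @export
scan_transitions <- function(m_values, n_realizations, n = 80, model = "er",
                             inputs = c("all", "random"),
                             targets = c("kappa_c", "kappa_m"),
                             p = 1, tmax = 300, n_runs = 30,
                             compute_pm = FALSE, pm_p = 0.5, seed = NULL) {
  inputs <- match.arg(inputs)
  targets <- match.arg(targets, several.ok = TRUE)
  model <- match.arg(model, c("er", "ba"))
  gseeds <- derive_seeds(seed, length(m_values) * n_realizations)
  rows <- list()
  idx <- 0L
  for (mi in seq_along(m_values)) {
    for (rep in seq_len(n_realizations)) {
      idx <- idx + 1L
      gs <- if (is.null(gseeds)) NULL else gseeds[idx]
      if (model == "er") {
        g <- graph_er(n, m_values[mi], seed = gs)
        m_realized <- m_values[mi]
      } else {
        map <- ba_m_for_edges(n, m_values[mi])
        g <- graph_ba(n, map$m, seed = gs)
        m_realized <- map$m_realized
      }
      node_seeds <- derive_seeds(bump_seed(gs, 1), n)
      input_set <- if (inputs == "all") seq_len(n) else {
        with_seed_or_not(bump_seed(gs, 2), sample.int(n, 1L))
      }
      for (inp in input_set) {
        lv <- layered_view(g, inp)
        if (!length(lv$output_layer)) next
        ns <- if (is.null(node_seeds)) NULL else node_seeds[inp]
        ch <- derive_seeds(ns, 3)
        out <- select_output_node(lv, seed = if (is.null(ch)) NULL else ch[1])
        pred <- topological_predictors(g, inp, out)
        kc <- find_kappa_c(g, inp, out, p = p, tmax = tmax, n_runs = n_runs,
                           seed = if (is.null(ch)) NULL else ch[2])
        row <- data.frame(
          m_edges = m_values[mi], m_realized = m_realized, graph_id = idx,
          input = inp, output = out,
          disconnected = length(lv$unreachable) > 0,
          k_star = pred$k_star, k_double_star = pred$k_double_star,
          k_max = pred$k_max, k_max1 = pred$k_max1,
          inv_kappa_c = kc$value, inv_kappa_c_rounded = kc$rounded,
          status_c = kc$status
        )
        if ("kappa_m" %in% targets) {
          km <- find_kappa_m(g, inp, out, p = p, tmax = tmax, n_runs = n_runs,
                             seed = if (is.null(ch)) NULL else ch[3],
                             onset = kc)
          row$inv_kappa_m <- km$value
          row$inv_kappa_m_rounded <- km$rounded
          row$status_m <- km$status
        }
        if (compute_pm) {
          row$p_m <- multiple_excitation_probability(
            g, kappa = 1 / pred$k_star, p = pm_p)
        }
        rows[[length(rows) + 1L]] <- row
      }
    }
  }
  do.call(rbind, rows)
}

#' Prediction quality of a topological predictor
#'
#' The percentage of trials in which a predictor equals the rounded measured
#' transition value, per edge count M. Trials whose measurement carries a
#' sentinel status (`no_propagation` for the onset; `none` or
#' `no_propagation` for the limit) are excluded from the denominator and
#' counted separately.
#'
#' @param trials A data.frame from [scan_transitions()].
#' @param predictor One of `"k_star"`, `"k_double_star"`, `"k_max"`,
#'   `"k_max1"`.
#' @param target `"kappa_c"` or `"kappa_m"`.
#' @return A data.frame with one row per `m_edges`: `quality` (0-100), `n`
#'   (trials in the denominator), `n_excluded`.
#' @export
prediction_quality <- function(trials,
                               predictor = c("k_star", "k_double_star",
                                             "k_max", "k_max1"),
                               target = c("kappa_c", "kappa_m")) {
  predictor <- match.arg(predictor)
  target <- match.arg(target)
  meas_col <- if (target == "kappa_c") "inv_kappa_c_rounded"
              else "inv_kappa_m_rounded"
  if (!meas_col %in% names(trials)) {
    stop("trials table lacks measurements for target ", target)
  }
  ok <- !is.na(trials[[meas_col]])
  out <- lapply(split(trials, trials$m_edges), function(d) {
    use <- !is.na(d[[meas_col]])
    data.frame(
      m_edges = d$m_edges[1],
      quality = if (any(use)) {
        100 * mean(d[[predictor]][use] == d[[meas_col]][use])
      } else NA_real_,
      n = sum(use),
      n_excluded = sum(!use)
    )
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res[order(res$m_edges), ]
}

#' Saturation scan: maximal output level over the 1/kappa grid
#'
#' For each graph of an ensemble, runs the single-excitation experiment over
#' a grid of 1/kappa values and records the maximal accumulated output count
#' together with the inter-excitation periods of the output node at the
#' maximizing grid value. In the saturated regime with `p = 1` the output
#' node is re-excited by cycling activity with the minimal period 3
#' (E -> R -> S), so the maximal count approaches `tmax / 3`.
#'
#' @param n_graphs Number of graph realizations.
#' @param n,m_edges,model Graph ensemble parameters (see
#'   [scan_transitions()]).
#' @param p,tmax Dynamics parameters.
#' @param grid Grid of 1/kappa values (default 1..50).
#' @param n_runs Stochastic repetitions per grid value (the per-graph
#'   maximum is over all grid values and runs).
#' @param seed Root seed.
#' @return A data.frame with one row per graph: `graph_id`, `input`,
#'   `output`, `best_inv_kappa`, `max_count`, `min_period` (smallest gap
#'   between successive output excitations in the second half of the run at
#'   the maximizing grid value; `NA` when fewer than two such excitations).
#' @export
saturation_scan <- function(n_graphs, n = 80, m_edges = 640, model = "er",
                            p = 1, tmax = 300, grid = 1:50, n_runs = 1,
                            seed = NULL) {
  model <- match.arg(model, c("er", "ba"))
  gseeds <- derive_seeds(seed, n_graphs)
  rows <- lapply(seq_len(n_graphs), function(i) {
    gs <- if (is.null(gseeds)) NULL else gseeds[i]
    g <- if (model == "er") graph_er(n, m_edges, seed = gs) else {
      graph_ba(n, ba_m_for_edges(n, m_edges)$m, seed = gs)
    }
    ch <- derive_seeds(gs, 3)
    lv_ok <- FALSE
    inp <- NA_integer_
    cand <- with_seed_or_not(if (is.null(ch)) NULL else ch[1],
                             sample.int(n))
    for (v in cand) {  # first non-isolated node in random order
      lv <- layered_view(g, v)
      if (length(lv$output_layer)) { inp <- v; lv_ok <- TRUE; break }
    }
    if (!lv_ok) stop("ensemble graph has no usable input node")
    out <- select_output_node(lv, seed = if (is.null(ch)) NULL else ch[2])
    run_seeds <- derive_seeds(if (is.null(ch)) NULL else ch[3],
                              length(grid) * n_runs)
    best <- list(count = -1L, x = NA_real_, times = integer(0))
    k <- 0L
    for (x in grid) {
      for (r in seq_len(n_runs)) {
        k <- k + 1L
        d <- run_single(g, inp, out, x, p = p, tmax = tmax,
                        seed = if (is.null(run_seeds)) NULL else run_seeds[k],
                        detail = TRUE)
        if (d$count > best$count) best <- list(count = d$count, x = x,
                                               times = d$times)
      }
    }
    late <- best$times[best$times > tmax / 2]
    gaps <- diff(late)
    data.frame(
      graph_id = i, input = inp, output = out,
      best_inv_kappa = best$x, max_count = best$count,
      min_period = if (length(gaps)) min(gaps) else NA_integer_
    )
  })
  do.call(rbind, rows)
}

#' Mean saturation level of an ensemble, normalized to the p = 1 capacity
#'
#' Runs [saturation_scan()] and reports the ensemble mean of the per-graph
#' maximal output counts, normalized so that 100 corresponds to the maximal
#' capacity of the output node under deterministic recovery, `tmax / 3`
#' (one excitation per minimal E-R-S cycle). The mean-field prediction for
#' the un-normalized level is `a_max = tmax / (2 + 1/p)` (see [a_max()]).
#'
#' @inheritParams saturation_scan
#' @return A list with `level` (normalized, 100 = deterministic capacity),
#'   `mean_max` (raw mean of per-graph maxima), and `per_graph` (the
#'   [saturation_scan()] table).
#' @export
saturation_level <- function(n_graphs, n = 80, m_edges = 640, model = "er",
                             p = 1, tmax = 300, grid = 1:50, n_runs = 1,
                             seed = NULL) {
  sc <- saturation_scan(n_graphs, n = n, m_edges = m_edges, model = model,
                        p = p, tmax = tmax, grid = grid, n_runs = n_runs,
                        seed = seed)
  mean_max <- mean(sc$max_count)
  list(level = 100 * mean_max / (tmax / 3), mean_max = mean_max,
       per_graph = sc)
}
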