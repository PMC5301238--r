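#' Mean-field steady-state activity densities
#'
#' The homogeneous mean-field description of the dynamics evolves the
#' excited fraction as `c_E(t+1) = c_S(t) * H(c_E(t) - kappa)` (H the
#' Heaviside step), with `c_S = 1 - c_E - c_R` and `c_R = c_E / p` (each
#' excitation is followed by a refractory episode of mean length `1/p`).
#' When `kappa < p / (2p + 1)` the map has the active fixed point
#' `c_E = p / (2p + 1)` (equivalently `1 / (2 + 1/p)`), with `c_S = c_E` and
#' `c_R = c_E / p`; otherwise the excitation gate closes and the dynamics
#' collapses to the extinct state `(c_E, c_S, c_R) = (0, 1, 0)`.
#'
#' @param kappa Relative excitation threshold in (0, 1].
#' @param p Recovery probability in (0, 1].
#' @return A list of class `ser_densities` with `c_e`, `c_s`, `c_r` (summing
#'   to 1) and the logical `active`.
#' @examples
#' steady_state_density(0.1, 1)    # (1/3, 1/3, 1/3)
#' steady_state_density(0.5, 1)    # extinct: kappa >= 1/3
#' @export
steady_state_density <- function(kappa, p) {
  stopifnot(kappa > 0, kappa <= 1, p > 0, p <= 1)
  ce <- p / (2 * p + 1)
  if (kappa < ce) {
    structure(list(c_e = ce, c_s = ce, c_r = ce / p, active = TRUE),
              class = "ser_densities")
  } else {
    structure(list(c_e = 0, c_s = 1, c_r = 0, active = FALSE),
              class = "ser_densities")
  }
}

#' @export
print.ser_densities <- function(x, ...) {
  cat(sprintf("mean-field densities: c_E = %.4f, c_S = %.4f, c_R = %.4f (%s)\n",
              x$c_e, x$c_s, x$c_r,
              if (x$active) "active" else "extinct"))
  invisible(x)
}

#' Iterate the mean-field map (numerical oracle for the fixed point)
#'
#' Solves the mean-field self-consistency `c_E = c_S * H(c_E - kappa)` with
#' `c_S = 1 - c_E - c_R` and `c_R = c_E / p` by damped fixed-point
#' iteration from a given starting excitation density. Used to cross-check
#' the closed-form fixed point of [steady_state_density()].
#'
#' The relaxation factor is needed because the raw synchronous map has slope
#' `-(1 + 1/p)` at the active fixed point: undamped iteration overshoots,
#' oscillates below the threshold and collapses to extinction from generic
#' starting points. The default damping `1 / (2 + 1/p)` cancels the slope
#' at the fixed point; the closed form is separately asserted to be exactly
#' invariant under the undamped map in the test suite.
#'
#' @param kappa,p Model parameters.
#' @param c_e0 Initial excited fraction.
#' @param iterations Number of iterations.
#' @param damping Relaxation factor in (0, 1]; `NULL` for the default.
#' @return The excited fraction after `iterations` steps.
#' @export
iterate_meanfield_map <- function(kappa, p, c_e0 = 0.5, iterations = 500,
                                  damping = NULL) {
  if (is.null(damping)) damping <- 1 / (2 + 1 / p)
  ce <- c_e0
  for (i in seq_len(iterations)) {
    f <- if (ce - kappa >= 0) max(0, 1 - ce * (1 + 1 / p)) else 0
    ce <- (1 - damping) * ce + damping * f
  }
  ce
}

#' Probability that a barrier is passed by concurrent excitations
#'
#' A node of degree `k` is a barrier of strength `n = ceiling(kappa * k)`:
#' it needs `n` simultaneously excited neighbours. In the mean-field closure
#' each neighbour is independently excited with probability `c_e`, so the
#' barrier is passed with the binomial tail probability `P(Bin(k, c_e) >=
#' n)` (`mode = "homogeneous"`, appropriate when excitations wander along
#' complicated paths and can reach the barrier by any edge). In
#' `mode = "front"` only the `k_in` edges arriving from the next upper layer
#' of the layered view carry excitations, and the tail is averaged over a
#' supplied distribution of `k_in`.
#'
#' With `tail = FALSE` the point-mass variant `P(Bin == n)` is returned
#' instead (exactly `n` excited neighbours); the tail is the default, since
#' passing a strength-`n` barrier requires at least `n` concurrent
#' excitations.
#'
#' @param k Barrier degree.
#' @param kappa Relative excitation threshold in (0, 1].
#' @param c_e Neighbour excitation probability (mean-field density).
#' @param mode `"homogeneous"` (use all `k` edges) or `"front"` (average
#'   over `kin_dist`).
#' @param kin_dist For `mode = "front"`: a numeric vector of probabilities
#'   over `k_in = 0..k` (length `k + 1`), e.g. from [kin_distribution()].
#' @param tail Use the tail (`>= n`, default) or point-mass (`== n`)
#'   probability.
#' @return A probability.
#' @examples
#' barrier_pass_probability(4, 0.3, 0.25)  # P(Bin(4, 1/4) >= 2) = 67/256
#' @export
barrier_pass_probability <- function(k, kappa, c_e,
                                     mode = c("homogeneous", "front"),
                                     kin_dist = NULL, tail = TRUE) {
  mode <- match.arg(mode)
  stopifnot(k >= 0, c_e >= 0, c_e <= 1)
  n <- barrier_strength(k, kappa)
  if (k == 0) return(0)
  prob_at_least <- function(size) {
    if (n > size) return(0)
    if (tail) stats::pbinom(n - 1, size, c_e, lower.tail = FALSE)
    else stats::dbinom(n, size, c_e)
  }
  if (mode == "homogeneous") {
    prob_at_least(k)
  } else {
    if (is.null(kin_dist)) stop("mode = 'front' requires kin_dist")
    if (length(kin_dist) != k + 1) stop("kin_dist must have length k + 1")
    sum(kin_dist * vapply(0:k, prob_at_least, numeric(1)))
  }
}

#' Empirical distribution of incoming-layer link counts
#'
#' For the front-mode barrier computation: the conditional distribution of
#' the number of edges a degree-`k` node sends to its upper layer (one BFS
#' level closer to the input node), estimated from the layered view of a
#' given graph.
#'
#' @param graph An igraph object.
#' @param input Input node defining the layered view.
#' @param k Degree to condition on.
#' @return A numeric probability vector over `k_in = 0..k` (length `k + 1`);
#'   uniform over observed values, zero vector if no degree-`k` node is
#'   reachable.
#' @export
kin_distribution <- function(graph, input, k) {
  lv <- layered_view(graph, input)
  deg <- igraph::degree(graph)
  adj <- igraph::as_adj_list(graph)
  nodes <- which(deg == k & is.finite(lv$dist) & lv$dist > 0)
  out <- numeric(k + 1)
  if (!length(nodes)) return(out)
  for (v in nodes) {
    kin <- sum(lv$dist[as.integer(adj[[v]])] == lv$dist[v] - 1)
    out[kin + 1] <- out[kin + 1] + 1
  }
  out / sum(out)
}

#' Mean-field probability of barrier passage by multiple excitations P_m
#'
#' The probability that concurrent multiple excitations let the signal pass
#' a barrier (a node requiring at least two simultaneously excited
#' neighbours), estimated in the homogeneous mean-field closure: neighbours
#' of a degree-`k` node are independently excited with the steady-state
#' density `c_E*` of [steady_state_density()], and the binomial tail is
#' averaged over the graph's degree distribution, summed over all barrier
#' strengths `n >= 2`. `1 - P_m` quantifies the confidence in the
#' single-excitation predictor `k*` of the propagation onset: multiple
#' excitations are what invalidate it, and they are the more frequent the
#' denser the network.
#'
#' @param graph An igraph object.
#' @param kappa Relative excitation threshold in (0, 1].
#' @param p Recovery probability (sets the steady-state density).
#' @param tail Passed to [barrier_pass_probability()].
#' @return A probability in \[0, 1\].
#' @export
multiple_excitation_probability <- function(graph, kappa, p, tail = TRUE) {
  dens <- steady_state_density(kappa, p)
  if (!dens$active) return(0)
  deg <- igraph::degree(graph)
  n <- barrier_strength(deg, kappa)
  pass <- vapply(seq_along(deg), function(i) {
    if (n[i] < 2) return(0)
    barrier_pass_probability(deg[i], kappa, dens$c_e, tail = tail)
  }, numeric(1))
  mean(pass)
}

#' Mean-field ceiling of the accumulated output level
#'
#' In the saturated amplification regime the output node is periodically
#' re-excited by cycling activity; one full E -> R -> S cycle takes one
#' excited step, one refractory step of mean duration `1/p`, and one step to
#' be re-excited, i.e. an average period `2 + 1/p`. Over a recording of
#' `tmax` steps the accumulated output level is therefore at most
#' `a_max = tmax / (2 + 1/p)`.
#'
#' @param p Recovery probability in (0, 1].
#' @param tmax Recording duration T.
#' @return The predicted maximal accumulated output excitation count.
#' @examples
#' a_max(1, 300)    # 100
#' a_max(0.5, 300)  # 75
#' @export
a_max <- function(p, tmax) {
  stopifnot(p > 0, p <= 1, tmax >= 1)
  tmax / (2 + 1 / p)
}
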