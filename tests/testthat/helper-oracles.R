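# Independent oracles used to cross-check the package's algorithms. They are
# deliberately naive (enumeration / brute force) and share no code with the
# implementation paths they verify.

# Minimax-path degree by exhaustive enumeration of all simple paths
# (excluding the input node's degree, including the output node's).
brute_minimax <- function(graph, input, output) {
  deg <- igraph::degree(graph)
  paths <- igraph::all_simple_paths(graph, from = input, to = output)
  if (!length(paths)) return(NA_integer_)
  min(vapply(paths, function(p) {
    v <- as.integer(p)[-1]  # drop the input node
    max(deg[v])
  }, numeric(1)))
}

# Barrier-pass probability by enumeration of all 2^k excited/not
# configurations of the neighbours.
brute_pass_prob <- function(k, kappa, c_e, tail = TRUE) {
  n <- ceiling(k * kappa - 1e-9)
  total <- 0
  for (bits in 0:(2^k - 1)) {
    exc <- sum(bitwAnd(bits, 2^(0:(k - 1))) > 0)
    hit <- if (tail) exc >= n else exc == n
    if (hit) total <- total + c_e^exc * (1 - c_e)^(k - exc)
  }
  total
}

# Reference SER trajectory via the (tested) R stepper, used to check the
# compiled core.
r_trajectory <- function(graph, init, kappa, p, tmax) {
  states <- matrix(NA_integer_, nrow = tmax + 1, ncol = length(init))
  states[1, ] <- init
  s <- init
  for (t in seq_len(tmax)) {
    s <- ser_step(graph, s, kappa, p)
    states[t + 1, ] <- s
  }
  states
}

# Small named graphs used across test files.
toy_graphs <- function() {
  fx <- fixture_graphs()
  fx[c("path5", "star", "triangle", "diamond", "tree")]
}
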