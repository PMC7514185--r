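#' Four-node ring network fixture
#'
#' The reference test network: four integrate-and-fire nodes coupled in a
#' directed ring `1 -> 2 -> 3 -> 4 -> 1`, two excitatory and two
#' inhibitory, every coupling strength 0.02, with the reference parameter
#' set (`x_ex = 14/3`, `x_in = -2/3`, `sigma_ex = 2` ms, `sigma_in = 5`
#' ms, `tau = 20` ms, `x_th = 1`, `x_r = 0`, `tau_ref = 2` ms, background
#' `mu = 0.1` per ms with jump `f = 0.1`). Under these parameters each
#' node fires at roughly 50 Hz. Nodes 1 and 3 are excitatory, 2 and 4
#' inhibitory; the structurally independent pairs `{1,3}` and `{2,4}` do
#' not depend on that assignment (the conclusion is
#' orientation-invariant).
#'
#' The magnitude `f` is treated as a dimensionless conductance jump (not a
#' rate): each background arrival increments `g_bg` by `f`.
#'
#' @param node_sign sign assignment, by default alternating
#'   excitatory/inhibitory around the ring.
#' @param strength coupling strength for every edge.
#' @return a list with elements `graph` (a [coupling_graph]) and `params`
#'   (an [if_params]).
#' @export
ring4_network <- function(node_sign = c("excitatory", "inhibitory",
                                        "excitatory", "inhibitory"),
                          strength = 0.02) {
  edges <- rbind(c(1L, 2L), c(2L, 3L), c(3L, 4L), c(4L, 1L))
  list(graph = coupling_graph(4L, edges, node_sign = node_sign,
                              strength = strength),
       params = if_params())
}

#' Four-node chain-with-collider fixture
#'
#' A second small network in which nodes 1 and 3 form the only
#' structurally independent pair: edges `1 -> 2`, `2 -> 1`, `2 -> 3`,
#' `3 -> 4`, `4 -> 2`, so `U_1 = {1,2}` and `U_3 = {3,4}` are disjoint
#' while every other pair is connected or shares a child. The exact wiring
#' of such published examples is not always fully recoverable, so the edge
#' set is configurable; the default is a documented guess with the stated
#' independence property.
#'
#' @param edges two-column edge matrix overriding the default wiring.
#' @param node_sign,strength as in [ring4_network()].
#' @return a list with elements `graph` and `params`.
#' @export
chain4_network <- function(edges = NULL,
                           node_sign = c("excitatory", "inhibitory",
                                         "excitatory", "inhibitory"),
                           strength = 0.02) {
  if (is.null(edges)) {
    edges <- rbind(c(1L, 2L), c(2L, 1L), c(2L, 3L), c(3L, 4L), c(4L, 2L))
  }
  list(graph = coupling_graph(4L, edges, node_sign = node_sign,
                              strength = strength),
       params = if_params())
}

#' Product (independent Bernoulli) distribution
#'
#' `P(V) = prod_i p_i^{sigma_i} (1 - p_i)^{1 - sigma_i}`: the null model
#' in which every node is independent, so every interaction of order two
#' or higher vanishes and `J_i = log(p_i / (1 - p_i))`.
#'
#' @param p_vector per-node activation probabilities, each in `(0, 1)`.
#' @return a [state_distribution].
#' @export
product_distribution <- function(p_vector) {
  p <- as.numeric(p_vector)
  stopifnot(all(p > 0), all(p < 1))
  n <- length(p)
  smat <- state_matrix(n)
  lp <- smat %*% log(p) + (1 - smat) %*% log(1 - p)
  state_distribution(exp(drop(lp)), n = n)
}

#' Distribution generated from a known set of effective interactions
#'
#' Builds the exact Boltzmann-form distribution for a sparse set of
#' interaction coefficients: ground truth for recovery tests.
#'
#' @param J_spec named numeric vector or list; names are comma-joined node
#'   ids (e.g. `"1,3"` for the pair `{1, 3}`).
#' @param n node count (`<= 20`).
#' @return a [state_distribution].
#' @examples
#' d <- known_interaction_distribution(c("1" = 0.5, "1,2" = -1), n = 3)
#' @export
known_interaction_distribution <- function(J_spec, n) {
  n <- as.integer(n)
  stopifnot(n >= 1L, n <= 20L)
  J <- numeric(2L^n)
  if (length(J_spec) > 0L) {
    masks <- vapply(strsplit(names(J_spec), ","), function(v) {
      subset_to_mask(as.integer(v), n)
    }, numeric(1))
    J[masks + 1L] <- unlist(J_spec)
  }
  mep_distribution(effective_interactions(J, logZ = 0, n = n))
}

#' Random positive distribution that factorizes over a dependency graph
#'
#' Draws a pairwise Markov random field on the given dependency graph:
#' random first-order coefficients on every node and random second-order
#' coefficients on every dependency edge, zero elsewhere. Every non-edge
#' pair of the graph is conditionally independent given all other nodes,
#' so the fixture realizes exactly the conditional-independence structure
#' the dependency graph predicts (interactions are supported on cliques
#' of size one and two).
#'
#' @param dep a [dependency_graph] (or a [coupling_graph], converted
#'   first).
#' @param seed integer seed.
#' @param scale standard deviation of the random coefficients.
#' @return a [state_distribution] with full support.
#' @export
markov_factorized_distribution <- function(dep, seed = 1L, scale = 1) {
  if (inherits(dep, "coupling_graph")) dep <- dependency_graph(dep)
  stopifnot(inherits(dep, "dependency_graph"), dep$n <= 12L)
  n <- dep$n
  coef <- withr::with_seed(as.integer(seed), {
    list(node = stats::rnorm(n, sd = scale),
         edge = stats::rnorm(nrow(dep$dep_edges), sd = scale))
  })
  J_spec <- c(stats::setNames(coef$node, as.character(seq_len(n))),
              if (nrow(dep$dep_edges) > 0L) {
                stats::setNames(coef$edge, paste(dep$dep_edges[, 1L],
                                                 dep$dep_edges[, 2L],
                                                 sep = ","))
              })
  known_interaction_distribution(J_spec, n)
}

#' Random full-support distribution
#'
#' Dirichlet-like draw: independent Gamma(shape) weights over all `2^n`
#' states, normalized. Useful as a generic full-support test input.
#'
#' @param n node count.
#' @param seed integer seed.
#' @param shape Gamma shape; larger values give more uniform draws.
#' @return a [state_distribution].
#' @export
random_distribution <- function(n, seed = 1L, shape = 5) {
  w <- withr::with_seed(as.integer(seed),
                        stats::rgamma(2L^n, shape = shape))
  state_distribution(w / sum(w), n = n)
}

#' Sample a raster i.i.d. from a state distribution
#'
#' Each time bin's state vector is drawn independently from `dist`.
#'
#' @param dist a [state_distribution].
#' @param NT number of time bins.
#' @param seed integer seed.
#' @param delta nominal bin width (ms) recorded on the raster.
#' @return a [binary_raster].
#' @export
sample_raster <- function(dist, NT, seed = 1L, delta = 10) {
  n <- dist$n
  masks <- withr::with_seed(as.integer(seed), {
    sample.int(2L^n, size = NT, replace = TRUE, prob = dist$probs) - 1L
  })
  states <- vapply(seq_len(n), function(i) {
    bitwAnd(bitwShiftR(masks, i - 1L), 1L)
  }, integer(NT))
  binary_raster(t(states), delta)
}
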