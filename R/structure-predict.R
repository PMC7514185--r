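#' Dependency graph of a coupling structure
#'
#' The undirected graph of "potentially dependent" node pairs: `{i, j}` is
#' an edge when `U_i` and `U_j` intersect, where `U_i = C(i) + {i}` and
#' `C(i)` is the set of child nodes of `i`. Equivalently, `i` and `j` are
#' linked when they are connected in either direction or share a common
#' child. Only subsets of nodes that form cliques of this graph can carry
#' non-zero effective interactions (when external inputs are independent
#' across nodes); node sign plays no role.
#'
#' @param graph a [coupling_graph].
#' @return an object of class `dependency_graph` with fields `n` and
#'   `dep_edges` (two-column matrix of unordered pairs, `i < j`).
#' @export
dependency_graph <- function(graph) {
  stopifnot(inherits(graph, "coupling_graph"))
  n <- graph$n
  kids <- children(graph)
  U <- lapply(seq_len(n), function(i) c(i, kids[[i]]))
  # membership matrix: node x U-set; pair is dependent iff the U-sets meet
  memb <- matrix(FALSE, n, n)
  for (i in seq_len(n)) memb[U[[i]], i] <- TRUE
  overlap <- crossprod(memb)            # overlap[i, j] = |U_i n U_j|
  idx <- which(upper.tri(overlap) & overlap > 0, arr.ind = TRUE)
  edges <- matrix(as.integer(idx), ncol = 2L)
  colnames(edges) <- c("i", "j")
  structure(list(n = n, dep_edges = edges[order(edges[, 1L], edges[, 2L]),
                                          , drop = FALSE]),
            class = "dependency_graph")
}

#' @export
print.dependency_graph <- function(x, ...) {
  cat("dependency_graph:", x$n, "nodes,", nrow(x$dep_edges),
      "dependent pairs\n")
  invisible(x)
}

#' Count predicted non-zero interactions per order
#'
#' The node subsets that can carry a non-zero effective interaction are
#' exactly the cliques of the dependency graph (any subset containing a
#' structurally independent pair has a vanishing coefficient). Counts are
#' obtained by exact enumeration: depth-bounded recursive expansion in a
#' fixed vertex order, so every clique is visited once. Counts beyond the
#' largest clique are zero.
#'
#' @param dep a [dependency_graph] (or a [coupling_graph], converted
#'   first).
#' @param k_max largest order to enumerate (default 25; orders above it
#'   are not counted).
#' @param budget maximum number of node expansions before aborting with a
#'   partial-result error (guards against overly dense graphs).
#' @return an object of class `order_counts` with fields `counts` (named
#'   numeric vector, order `"1"` ... `"k_max"`), `n`, `k_max`,
#'   `sparseness` (see [sparseness()]).
#' @export
count_nonzero_orders <- function(dep, k_max = 25L, budget = 1e9) {
  if (inherits(dep, "coupling_graph")) dep <- dependency_graph(dep)
  stopifnot(inherits(dep, "dependency_graph"))
  k_max <- as.integer(min(k_max, dep$n))
  res <- .cpp_count_cliques(dep$n, dep$dep_edges[, 1L], dep$dep_edges[, 2L],
                            k_max, budget)
  if (isTRUE(res$exhausted)) {
    stop("clique enumeration exceeded its expansion budget (", budget,
         "); the dependency graph is too dense for exact counting ",
         "at k_max = ", k_max)
  }
  counts <- res$counts
  names(counts) <- as.character(seq_len(k_max))
  out <- structure(list(counts = counts, n = dep$n, k_max = k_max),
                   class = "order_counts")
  out$sparseness <- sparseness(out)
  out
}

#' @export
print.order_counts <- function(x, ...) {
  cat("order_counts (n =", x$n, "): predicted non-zero interactions\n")
  nz <- x$counts[x$counts > 0]
  cat(" ", paste(sprintf("k=%s: %g", names(nz), nz), collapse = "  "), "\n")
  cat("  sparseness =", format(x$sparseness), "\n")
  invisible(x)
}

#' Sparseness of the predicted interaction structure
#'
#' The ratio of the number of potentially non-zero effective interactions
#' (all orders `k = 1 ... n`; every first-order coefficient counts, the
#' constant normalization term does not) to the `2^n` possible
#' interactions.
#'
#' @param counts an [count_nonzero_orders()] result, or a bare named
#'   vector of per-order counts.
#' @param n node count (taken from `counts` when it is an `order_counts`).
#' @return `sum(counts) / 2^n` as a double.
#' @export
sparseness <- function(counts, n = NULL) {
  if (inherits(counts, "order_counts")) {
    n <- counts$n
    counts <- counts$counts
  }
  if (is.null(n)) stop("`n` is required for a bare count vector")
  sum(counts) / 2^n
}

#' Ensemble experiment over Erdos-Renyi coupling graphs
#'
#' Samples `n_networks` directed Erdos-Renyi graphs (each ordered pair
#' connected independently with probability `p`), computes each one's
#' dependency graph, per-order clique counts and sparseness, and returns
#' ensemble means and standard deviations. Networks whose clique
#' enumeration exceeds the expansion budget are skipped and counted in
#' `n_failed`.
#'
#' @param n nodes per network.
#' @param p connection probability.
#' @param n_networks ensemble size.
#' @param k_max,budget passed to [count_nonzero_orders()].
#' @param seed integer seed; network `s` uses seed `seed + s - 1`.
#' @return a list with `mean`, `sd` (named per-order vectors),
#'   `sparseness` (vector over networks), `mean_sparseness`,
#'   `counts` (matrix networks x orders), `n_failed`, and the call
#'   parameters.
#' @export
er_experiment <- function(n = 100L, p = 0.05, n_networks = 20L,
                          k_max = 25L, seed = 1L, budget = 1e9) {
  stopifnot(n_networks >= 1L)
  k_max <- as.integer(min(k_max, n))
  counts <- matrix(NA_real_, n_networks, k_max,
                   dimnames = list(NULL, as.character(seq_len(k_max))))
  sp <- rep(NA_real_, n_networks)
  n_failed <- 0L
  for (s in seq_len(n_networks)) {
    g <- er_graph(n, p, seed = as.integer(seed) + s - 1L)
    oc <- tryCatch(count_nonzero_orders(dependency_graph(g), k_max = k_max,
                                        budget = budget),
                   error = function(e) NULL)
    if (is.null(oc)) {
      n_failed <- n_failed + 1L
      next
    }
    counts[s, ] <- oc$counts
    sp[s] <- oc$sparseness
  }
  if (n_failed > 0L) {
    warning(n_failed, " network(s) exceeded the enumeration budget and ",
            "were skipped")
  }
  ok <- !is.na(sp)
  list(mean = colMeans(counts[ok, , drop = FALSE]),
       sd = apply(counts[ok, , drop = FALSE], 2L, stats::sd),
       sparseness = sp, mean_sparseness = mean(sp[ok]),
       counts = counts, n_failed = n_failed,
       n = n, p = p, n_networks = n_networks, k_max = k_max, seed = seed)
}

#' Write per-order counts (or an ensemble result) as JSON
#'
#' @param x an `order_counts` object or an [er_experiment()] result.
#' @param path file path.
#' @return `path`, invisibly.
#' @export
write_order_counts <- function(x, path) {
  if (inherits(x, "order_counts")) {
    payload <- list(n = x$n, counts = as.list(x$counts),
                    sparseness = x$sparseness)
  } else {
    payload <- list(n = x$n, p = x$p, n_networks = x$n_networks,
                    mean = as.list(x$mean), sd = as.list(x$sd),
                    mean_sparseness = x$mean_sparseness)
  }
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
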