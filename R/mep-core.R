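#' Effective interactions of a maximum-entropy model
#'
#' The maximum-entropy distribution over binary network states subject to
#' moment constraints up to order `m` has the Boltzmann form
#' `P(V) = exp(sum_A J_A prod_{i in A} sigma_i) / Z`, where `A` runs over
#' non-empty node subsets of size at most `m`. `J_A` is called the
#' `|A|`-th-order effective interaction and `Z` is the partition function.
#'
#' Internally `J` is stored as a dense vector over subset masks; use
#' [interaction()] to read a single coefficient or [interaction_table()]
#' for all of them.
#'
#' @param J numeric vector of length `2^n`; entry `mask + 1` is the
#'   coefficient of the subset with that mask. Entry 1 (the empty set) is
#'   ignored and stored as 0.
#' @param logZ log partition function.
#' @param n node count.
#' @return an object of class `effective_interactions`.
#' @export
effective_interactions <- function(J, logZ, n = NULL) {
  J <- as.numeric(J)
  if (is.null(n)) n <- as.integer(round(log2(length(J))))
  if (length(J) != 2L^n) stop("`J` must have length 2^n")
  if (any(!is.finite(J)) || !is.finite(logZ)) {
    stop("interactions and logZ must be finite")
  }
  J[1L] <- 0
  structure(list(n = as.integer(n), J = J, logZ = as.numeric(logZ)),
            class = "effective_interactions")
}

#' @export
print.effective_interactions <- function(x, ...) {
  cat("effective_interactions over", x$n, "nodes, logZ =",
      signif(x$logZ, 6), "\n")
  tab <- interaction_table(x)
  tab <- tab[order(-abs(tab$J)), ]
  k <- min(8L, nrow(tab))
  for (r in seq_len(k)) {
    cat(sprintf("  J_{%s} = %s\n", tab$subset[r], signif(tab$J[r], 6)))
  }
  if (nrow(tab) > k) cat("  ...\n")
  invisible(x)
}

#' Read one effective interaction coefficient
#'
#' @param ints an [effective_interactions] object.
#' @param subset vector of distinct node ids in `[1, n]`.
#' @return the coefficient `J_subset`.
#' @export
interaction <- function(ints, subset) {
  ints$J[subset_to_mask(subset, ints$n) + 1L]
}

#' All interactions as a data frame
#'
#' @param ints an [effective_interactions] object.
#' @param order optional vector of orders to keep.
#' @return data.frame with columns `subset` (comma-joined node ids),
#'   `order`, `J`, ordered by order then subset.
#' @export
interaction_table <- function(ints, order = NULL) {
  n <- ints$n
  sizes <- mask_sizes(n)
  keep <- which(sizes >= 1L)
  if (!is.null(order)) keep <- keep[sizes[keep] %in% order]
  subs <- vapply(keep - 1L, function(mask) {
    paste(mask_to_subset(mask, n), collapse = ",")
  }, character(1))
  out <- data.frame(subset = subs, order = sizes[keep], J = ints$J[keep],
                    stringsAsFactors = FALSE)
  out[order(out$order, out$subset), , drop = FALSE]
}

check_full_support <- function(dist, pseudocount) {
  probs <- dist$probs
  if (pseudocount > 0) {
    probs <- probs + pseudocount / length(probs)
    probs <- probs / sum(probs)
  } else if (any(probs <= 0)) {
    bad <- state_labels(dist$n)[which(probs <= 0)[1]]
    stop("state ", bad, " has zero probability; the full-order solution ",
         "needs full support (insufficient sampling?). Set `pseudocount` ",
         "to regularize explicitly.")
  }
  probs
}

#' Exact full-order effective interactions from a state distribution
#'
#' Solves the full-order (order `m = n`) maximum-entropy model, whose
#' unique solution is the observed distribution itself, for its
#' interaction coefficients: taking logs of the Boltzmann form gives a
#' triangular linear system over the subset lattice whose solution is the
#' Moebius inversion
#' `J_A = sum_{B subseteq A} (-1)^{|A| - |B|} log P(V_B)`,
#' where `V_B` is the state activating exactly the nodes in `B`. The log
#' partition function is `-log P(0...0)`.
#'
#' @param dist a [state_distribution] with full support.
#' @param pseudocount optional Laplace mass `alpha` added as `alpha / 2^n`
#'   occupancy to every state before normalizing (default 0: a
#'   zero-probability state is an error). Any regularization is recorded
#'   in the returned object's `pseudocount` field.
#' @return an [effective_interactions] object; forward evaluation via
#'   [mep_distribution()] reproduces `dist` exactly (up to rounding).
#' @export
full_order_interactions <- function(dist, pseudocount = 0) {
  stopifnot(inherits(dist, "state_distribution"))
  probs <- check_full_support(dist, pseudocount)
  J <- subset_mobius(log(probs), dist$n)
  out <- effective_interactions(J, logZ = -log(probs[1L]), n = dist$n)
  out$pseudocount <- pseudocount
  out
}

#' Effective interactions by the conditional log-odds recursion
#'
#' Computes a single coefficient `J_A` by the recursive construction: the
#' first-order term is the log-odds of one node with all others silent,
#' `J_i = log P(sigma_i = 1, rest 0) / P(all 0)`, and each higher order is
#' obtained by switching one more node from silent to active and
#' subtracting, `J_{A + k} = J_A^{(k active)} - J_A`. This is an
#' independent route to the same coefficients as
#' [full_order_interactions()].
#'
#' @param dist a [state_distribution] with full support.
#' @param subset vector of distinct node ids.
#' @param pseudocount as in [full_order_interactions()].
#' @return the coefficient `J_subset`.
#' @export
recursive_interaction <- function(dist, subset, pseudocount = 0) {
  stopifnot(inherits(dist, "state_distribution"))
  n <- dist$n
  probs <- check_full_support(dist, pseudocount)
  subset <- sort(as.integer(subset))
  subset_to_mask(subset, n)  # validates
  logp <- log(probs)
  # rec(A, bg): J_A evaluated with the nodes outside A held at state `bg`
  rec <- function(A, bg_mask) {
    if (length(A) == 1L) {
      i_bit <- 2L^(A - 1L)
      return(logp[bg_mask + i_bit + 1L] - logp[bg_mask + 1L])
    }
    k <- A[length(A)]
    head <- A[-length(A)]
    k_bit <- 2L^(k - 1L)
    rec(head, bg_mask + k_bit) - rec(head, bg_mask)
  }
  rec(subset, 0L)
}

#' Basic-form conditional log-odds difference
#'
#' For a node pair `(i, j)` and a state `H` of the remaining `n - 2`
#' nodes, returns the difference of conditional log-odds of node `i`
#' between `sigma_j = 1` and `sigma_j = 0`:
#' `log [P(si=1|sj=1,H)/P(si=0|sj=1,H)] - log [P(si=1|sj=0,H)/P(si=0|sj=0,H)]`.
#' Every interaction containing both `i` and `j` is a signed sum of such
#' terms, so conditional independence of `i` and `j` given the rest forces
#' all of them to vanish.
#'
#' @param dist a [state_distribution].
#' @param i,j distinct node ids.
#' @param H state of the remaining nodes: 0/1 vector of length `n - 2`
#'   ordered by increasing node id, or a state string of that length.
#' @return the log-odds difference.
#' @export
basic_form <- function(dist, i, j, H) {
  n <- dist$n
  masks <- pair_condition_masks(n, i, j, H)
  p <- dist$probs[masks + 1L]   # order: (si=0,sj=0),(1,0),(0,1),(1,1)
  if (any(p <= 0)) {
    stop("a conditional probability in the basic form is undefined ",
         "(zero-probability conditioning state)")
  }
  log(p[4L] / p[3L]) - log(p[2L] / p[1L])
}

# Masks of the four joint states (sigma_i, sigma_j) in {0,1}^2 with the
# remaining nodes clamped at H.
pair_condition_masks <- function(n, i, j, H) {
  i <- as.integer(i); j <- as.integer(j)
  stopifnot(i != j, i >= 1L, j >= 1L, i <= n, j <= n)
  others <- setdiff(seq_len(n), c(i, j))
  if (is.character(H)) H <- as.integer(strsplit(H, "")[[1]])
  H <- as.integer(H)
  if (length(H) != n - 2L || !all(H %in% c(0L, 1L))) {
    stop("H must be a 0/1 state of the ", n - 2L, " remaining nodes")
  }
  base <- sum(H * 2^(others - 1L))
  bi <- 2^(i - 1L); bj <- 2^(j - 1L)
  c(base, base + bi, base + bj, base + bi + bj)
}

#' Forward maximum-entropy distribution from interactions
#'
#' Evaluates the Boltzmann form over all `2^n` states (via log-sum-exp, so
#' it cannot overflow) and normalizes. The stored `logZ` is ignored for
#' normalization and recomputed.
#'
#' @param ints an [effective_interactions] object.
#' @param n_cap refuse to enumerate more than `2^n_cap` states
#'   (default 20).
#' @return a [state_distribution]; round-tripping through
#'   [full_order_interactions()] is the identity.
#' @export
mep_distribution <- function(ints, n_cap = 20L) {
  stopifnot(inherits(ints, "effective_interactions"))
  if (ints$n > n_cap) {
    stop("refusing to enumerate 2^", ints$n, " states (n_cap = ", n_cap, ")")
  }
  e <- subset_zeta(ints$J, ints$n)      # sum of J_A over subsets of each V
  m <- max(e)
  logZ <- m + log(sum(exp(e - m)))
  state_distribution(exp(e - logZ), n = ints$n)
}

#' Low-order maximum-entropy fit by iterative proportional scaling
#'
#' Finds the order-`m` maximum-entropy model whose moments up to order `m`
#' match the targets. Starting from the uniform distribution (all `J = 0`)
#' the fitter cycles through the constrained subsets in subset-size order;
#' each update rescales the probability of the states containing the
#' subset so its moment matches exactly (classical iterative proportional
#' fitting, no damping), and accumulates the log-factor into `J_A`.
#'
#' @param target_moments named numeric vector as produced by [moments()]
#'   (names are comma-joined node ids), containing every non-empty subset
#'   of size at most `m`; or a [state_distribution] from which the moments
#'   are taken.
#' @param n node count (required when `target_moments` is a bare vector
#'   and the highest-order names do not determine it).
#' @param m constraint order, `1 <= m <= n`. With `m = n` the unique
#'   feasible solution is the observed distribution itself.
#' @param tol convergence tolerance on the worst absolute moment residual.
#' @param max_iter maximum number of full sweeps.
#' @return an [effective_interactions] object with `J` supported on
#'   subsets of size at most `m`, plus fields `iterations` and `residual`.
#' @export
fit_low_order <- function(target_moments, m, n = NULL, tol = 1e-10,
                          max_iter = 1000L) {
  if (inherits(target_moments, "state_distribution")) {
    n <- target_moments$n
    target_moments <- moments(target_moments, m)
  }
  if (is.null(n)) {
    n <- max(vapply(strsplit(names(target_moments), ","),
                    function(v) max(as.integer(v)), numeric(1)))
  }
  n <- as.integer(n)
  stopifnot(m >= 1L, m <= n)
  sizes <- mask_sizes(n)
  cons_masks <- which(sizes >= 1L & sizes <= m) - 1L
  cons_masks <- cons_masks[order(sizes[cons_masks + 1L], cons_masks)]
  key <- vapply(cons_masks, function(mask) {
    paste(mask_to_subset(mask, n), collapse = ",")
  }, character(1))
  if (!all(key %in% names(target_moments))) {
    stop("target_moments is missing subsets: ",
         paste(setdiff(key, names(target_moments)), collapse = " "))
  }
  t_A <- as.numeric(target_moments[key])
  if (any(t_A <= 0) || any(t_A >= 1)) {
    stop("iterative scaling requires target moments strictly inside (0, 1)")
  }
  smat <- state_matrix(n)
  # contains[[k]]: logical index of states containing constraint subset k
  contains <- lapply(cons_masks, function(mask) {
    idx <- mask_to_subset(mask, n)
    rowSums(smat[, idx, drop = FALSE]) == length(idx)
  })
  J <- numeric(2L^n)
  q <- rep(1 / 2^n, 2L^n)
  residual <- Inf
  iter <- 0L
  while (iter < max_iter) {
    iter <- iter + 1L
    for (k in seq_along(cons_masks)) {
      inA <- contains[[k]]
      S1 <- sum(q[inA])
      r <- t_A[k] * (1 - S1) / ((1 - t_A[k]) * S1)
      q[inA] <- q[inA] * r
      q <- q / sum(q)
      J[cons_masks[k] + 1L] <- J[cons_masks[k] + 1L] + log(r)
    }
    cur <- vapply(contains, function(inA) sum(q[inA]), numeric(1))
    residual <- max(abs(cur - t_A))
    if (residual < tol) break
  }
  if (residual >= tol) {
    stop("iterative scaling did not converge in ", max_iter,
         " sweeps (worst moment residual ", format(residual), ")")
  }
  e <- subset_zeta(J, n)
  mx <- max(e)
  logZ <- mx + log(sum(exp(e - mx)))
  out <- effective_interactions(J, logZ = logZ, n = n)
  out$iterations <- iter
  out$residual <- residual
  out
}

#' Write / read effective interactions as JSON
#'
#' The file holds `{"n": ..., "logZ": ..., "J": {"1": ..., "1,2": ...}}`
#' with subsets keyed by comma-joined sorted 1-based node ids. Zero
#' coefficients are written too, so the file is self-contained.
#'
#' @param ints an [effective_interactions] object.
#' @param path file path.
#' @return `read_interactions` returns an [effective_interactions];
#'   `write_interactions` returns `path` invisibly.
#' @export
write_interactions <- function(ints, path) {
  tab <- interaction_table(ints)
  jl <- as.list(tab$J)
  names(jl) <- tab$subset
  jsonlite::write_json(list(n = ints$n, logZ = ints$logZ, J = jl), path,
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_interactions
#' @export
read_interactions <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  n <- as.integer(x$n)
  J <- numeric(2L^n)
  masks <- vapply(strsplit(names(x$J), ","), function(v) {
    subset_to_mask(as.integer(v), n)
  }, numeric(1))
  J[masks + 1L] <- unlist(x$J)
  effective_interactions(J, logZ = x$logZ, n = n)
}
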