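# Brute-force oracles, deliberately written as direct enumerations so they
# share no code path with the package implementations they check.

# <prod_{i in A} sigma_i> by direct summation over all 2^n states.
oracle_moment <- function(dist, subset) {
  n <- dist$n
  total <- 0
  for (s in 0:(2^n - 1)) {
    bits <- bitwAnd(bitwShiftR(s, subset - 1L), 1L)
    if (all(bits == 1L)) total <- total + dist$probs[s + 1]
  }
  total
}

# J_A = sum_{B subseteq A} (-1)^{|A| - |B|} log P(V_B) by enumerating the
# subsets of A explicitly.
oracle_interaction <- function(dist, subset) {
  subset <- sort(subset)
  k <- length(subset)
  total <- 0
  for (b in 0:(2^k - 1)) {
    members <- subset[bitwAnd(bitwShiftR(b, seq_len(k) - 1L), 1L) == 1L]
    mask <- sum(2^(members - 1))
    total <- total + (-1)^(k - length(members)) * log(dist$probs[mask + 1])
  }
  total
}

# Per-size clique counts by scanning every one of the 2^n node subsets.
oracle_clique_counts <- function(dep, k_max = dep$n) {
  n <- dep$n
  adj <- matrix(FALSE, n, n)
  if (nrow(dep$dep_edges) > 0) {
    adj[dep$dep_edges] <- TRUE
    adj[dep$dep_edges[, c(2, 1), drop = FALSE]] <- TRUE
  }
  counts <- numeric(k_max)
  for (s in 1:(2^n - 1)) {
    members <- which(bitwAnd(bitwShiftR(s, 0:(n - 1)), 1L) == 1L)
    k <- length(members)
    if (k > k_max) next
    is_clique <- TRUE
    if (k >= 2) {
      pr <- utils::combn(members, 2)
      is_clique <- all(adj[t(pr)])
    }
    if (is_clique) counts[k] <- counts[k] + 1
  }
  names(counts) <- as.character(seq_len(k_max))
  counts
}

# A small random full-support distribution without using package helpers.
oracle_random_dist <- function(n, seed) {
  w <- withr::with_seed(seed, stats::runif(2^n, min = 0.05, max = 1))
  state_distribution(w / sum(w), n = n)
}
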