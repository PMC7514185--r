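#' Probability distribution over binary network states
#'
#' A `state_distribution` stores a full probability vector over the `2^n`
#' binary states of an `n`-node network. States are indexed internally by a
#' bit mask `0 .. 2^n - 1` in which bit `i - 1` carries the state of node
#' `i` (node 1 is the least significant bit), and externally by state
#' strings such as `"0110"` whose `i`-th character is the state of node `i`.
#'
#' @param probs numeric vector of length `2^n` (any `n >= 1`), non-negative.
#'   Position `s + 1` holds the probability of the state with mask `s`.
#' @param n node count; inferred from `length(probs)` when missing.
#' @param normalize if `TRUE`, rescale `probs` to sum to one.
#' @return an object of class `state_distribution` with fields `n` and
#'   `probs`.
#' @examples
#' d <- state_distribution(c(0.4, 0.2, 0.2, 0.2))
#' state_prob(d, "10")  # P(sigma1 = 1, sigma2 = 0)
#' @export
state_distribution <- function(probs, n = NULL, normalize = FALSE) {
  probs <- as.numeric(probs)
  if (is.null(n)) {
    n <- as.integer(round(log2(length(probs))))
  }
  if (length(probs) != 2L^n) {
    stop("`probs` must have length 2^n (got ", length(probs),
         " for n = ", n, ")")
  }
  if (any(!is.finite(probs)) || any(probs < 0)) {
    stop("probabilities must be finite and non-negative")
  }
  tot <- sum(probs)
  if (normalize) {
    if (tot <= 0) stop("cannot normalize: total mass is zero")
    probs <- probs / tot
  } else if (abs(tot - 1) > 1e-12) {
    stop("probabilities must sum to 1 within 1e-12 (sum = ", format(tot),
         "); use normalize = TRUE to rescale")
  }
  structure(list(n = as.integer(n), probs = probs),
            class = "state_distribution")
}

#' @export
print.state_distribution <- function(x, ...) {
  cat("state_distribution over", x$n, "nodes (", length(x$probs), "states )\n")
  k <- min(8L, length(x$probs))
  lab <- state_labels(x$n)[seq_len(k)]
  cat(paste0("  P(", lab, ") = ", signif(x$probs[seq_len(k)], 4),
             collapse = "\n"), "\n")
  if (length(x$probs) > k) cat("  ...\n")
  invisible(x)
}

#' State labels for an n-node network
#'
#' @param n node count.
#' @return character vector of length `2^n`; entry `s + 1` is the label of
#'   mask `s`, with the `i`-th character giving the state of node `i`.
#' @export
state_labels <- function(n) {
  vapply(0:(2L^n - 1L), mask_to_label, character(1), n = n)
}

mask_to_label <- function(mask, n) {
  paste(bitwAnd(bitwShiftR(mask, 0:(n - 1L)), 1L), collapse = "")
}

label_to_mask <- function(label) {
  bits <- as.integer(strsplit(label, "")[[1]])
  if (any(is.na(bits)) || any(bits > 1L)) stop("bad state label: ", label)
  sum(bits * 2L^(seq_along(bits) - 1L))
}

#' Look up the probability of one state
#'
#' @param dist a [state_distribution].
#' @param state a state string like `"0110"`, a 0/1 vector of length `n`,
#'   or an integer mask.
#' @return the probability of that state.
#' @export
state_prob <- function(dist, state) {
  dist$probs[state_mask(state, dist$n) + 1L]
}

state_mask <- function(state, n) {
  if (is.character(state)) {
    if (nchar(state) != n) stop("state string must have ", n, " characters")
    return(label_to_mask(state))
  }
  state <- as.integer(state)
  if (length(state) == n && all(state %in% c(0L, 1L))) {
    return(sum(state * 2L^(seq_len(n) - 1L)))
  }
  if (length(state) == 1L && state >= 0L && state < 2L^n) return(state)
  stop("cannot interpret state specification")
}

#' Matrix of all binary states
#'
#' @param n node count.
#' @return a `2^n x n` 0/1 matrix whose row `s + 1` is the state with mask
#'   `s`; column `i` is node `i`.
#' @export
state_matrix <- function(n) {
  s <- 0:(2L^n - 1L)
  vapply(seq_len(n), function(i) bitwAnd(bitwShiftR(s, i - 1L), 1L),
         integer(length(s)))
}

# Fast subset-sum (zeta) transform over the subset lattice:
# out[A] = sum_{B subseteq A} x[B].  x indexed by mask + 1.
subset_zeta <- function(x, n) {
  for (i in seq_len(n)) {
    bit <- 2L^(i - 1L)
    s <- 0:(length(x) - 1L)
    hi <- which(bitwAnd(s, bit) != 0L)
    x[hi] <- x[hi] + x[hi - bit]
  }
  x
}

# Inverse of subset_zeta (Moebius transform):
# out[A] = sum_{B subseteq A} (-1)^{|A| - |B|} x[B].
subset_mobius <- function(x, n) {
  for (i in seq_len(n)) {
    bit <- 2L^(i - 1L)
    s <- 0:(length(x) - 1L)
    hi <- which(bitwAnd(s, bit) != 0L)
    x[hi] <- x[hi] - x[hi - bit]
  }
  x
}

# Popcount of every mask 0 .. 2^n - 1.
mask_sizes <- function(n) {
  s <- 0:(2L^n - 1L)
  out <- integer(length(s))
  for (i in seq_len(n)) out <- out + bitwAnd(bitwShiftR(s, i - 1L), 1L)
  out
}

# Mask for a subset given as a vector of 1-based node ids.
subset_to_mask <- function(subset, n) {
  subset <- as.integer(subset)
  if (anyDuplicated(subset) || any(subset < 1L) || any(subset > n)) {
    stop("subset must be distinct node ids in [1, n]")
  }
  sum(2L^(subset - 1L))
}

mask_to_subset <- function(mask, n) {
  which(bitwAnd(bitwShiftR(mask, 0:(n - 1L)), 1L) == 1L)
}

#' Shannon entropy of a state distribution
#'
#' @param dist a [state_distribution].
#' @param base logarithm base (default `exp(1)`, i.e. nats).
#' @return entropy `-sum P log P` with `0 log 0 = 0`.
#' @export
distribution_entropy <- function(dist, base = exp(1)) {
  p <- dist$probs[dist$probs > 0]
  -sum(p * log(p)) / log(base)
}

#' Write / read a state distribution as JSON
#'
#' The file is a JSON map from state string (e.g. `"0110"`) to probability.
#'
#' @param dist a [state_distribution].
#' @param path file path.
#' @return `read_distribution` returns a [state_distribution];
#'   `write_distribution` returns `path` invisibly.
#' @export
write_distribution <- function(dist, path) {
  x <- as.list(dist$probs)
  names(x) <- state_labels(dist$n)
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_distribution
#' @export
read_distribution <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  n <- nchar(names(x)[1])
  probs <- numeric(2L^n)
  probs[vapply(names(x), label_to_mask, numeric(1)) + 1L] <- unlist(x)
  state_distribution(probs, n = n)
}
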