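#' Binary raster of network activity
#'
#' @param states `n x NT` 0/1 matrix; row `i` is node `i`, column `l` is
#'   time bin `l`.
#' @param delta bin width (ms).
#' @return an object of class `binary_raster` with fields `n`, `NT`,
#'   `delta`, `states`.
#' @export
binary_raster <- function(states, delta) {
  states <- as.matrix(states)
  if (!all(states %in% c(0L, 1L))) stop("raster entries must be 0 or 1")
  storage.mode(states) <- "integer"
  stopifnot(delta > 0)
  structure(list(n = nrow(states), NT = ncol(states),
                 delta = as.numeric(delta), states = states),
            class = "binary_raster")
}

#' @export
print.binary_raster <- function(x, ...) {
  cat("binary_raster:", x$n, "nodes x", x$NT, "bins of", x$delta, "ms\n")
  cat("  per-node activation:",
      paste(signif(rowMeans(x$states), 3), collapse = " "), "\n")
  invisible(x)
}

#' Bin spike trains into a binary raster
#'
#' Node `i` is active (`1`) in bin `l` if it fires at least once in the
#' half-open window `[(l-1) delta, l delta)` (bins reported 1-based). A
#' partial final bin is discarded, so `NT = floor(duration / delta)`.
#'
#' @param spikes a [spike_train_set].
#' @param delta bin width in ms (the reference analyses use 10 ms).
#' @return a [binary_raster].
#' @export
binarize <- function(spikes, delta = 10) {
  stopifnot(inherits(spikes, "spike_train_set"), delta > 0)
  NT <- floor(spikes$duration / delta)
  states <- matrix(0L, nrow = spikes$n, ncol = NT)
  if (nrow(spikes$spikes) > 0L && NT > 0L) {
    bin <- floor(spikes$spikes$time / delta) + 1L
    keep <- bin <= NT
    states[cbind(spikes$spikes$node[keep], bin[keep])] <- 1L
  }
  binary_raster(states, delta)
}

#' Empirical state distribution of a raster
#'
#' `P(V)` is the fraction of time bins whose binary state vector equals
#' `V`.
#'
#' @param raster a [binary_raster].
#' @return a [state_distribution].
#' @export
empirical_distribution <- function(raster) {
  stopifnot(inherits(raster, "binary_raster"), raster$NT >= 1L)
  w <- 2^(seq_len(raster$n) - 1)
  masks <- as.integer(round(colSums(raster$states * w)))
  probs <- tabulate(masks + 1L, nbins = 2L^raster$n) / raster$NT
  state_distribution(probs, n = raster$n)
}

#' Moments of a state distribution up to a given order
#'
#' Returns the expectations `<sigma_{i1} ... sigma_{iM}>` for every
#' non-empty node subset of size at most `m`.
#'
#' @param dist a [state_distribution].
#' @param m maximum order, `1 <= m <= n`.
#' @return named numeric vector; names are comma-joined sorted node ids
#'   (e.g. `"1,3"`).
#' @export
moments <- function(dist, m) {
  n <- dist$n
  stopifnot(m >= 1L, m <= n)
  # <prod_{i in A} sigma_i> = sum over states V with V superset A of P(V):
  # a superset-sum, i.e. a zeta transform on the complemented lattice.
  full <- 2L^n - 1L
  x <- rev(dist$probs)                  # reindex mask -> complement
  x <- subset_zeta(x, n)
  sup <- rev(x)                         # sup[A + 1] = sum_{V >= A} P(V)
  sizes <- mask_sizes(n)
  keep <- which(sizes >= 1L & sizes <= m)
  out <- sup[keep]
  names(out) <- vapply(keep - 1L, function(mask) {
    paste(mask_to_subset(mask, n), collapse = ",")
  }, character(1))
  out[order(sizes[keep], names(out))]
}

#' Shuffle surrogate of a raster
#'
#' Independently and uniformly permutes each node's sequence of time bins.
#' Per-node totals (hence all first moments) are preserved exactly while
#' cross-node correlations are destroyed in expectation.
#'
#' @param raster a [binary_raster].
#' @param seed integer seed; the same seed reproduces the same surrogate.
#' @return a [binary_raster] of the same shape.
#' @export
shuffle_raster <- function(raster, seed) {
  stopifnot(inherits(raster, "binary_raster"))
  if (raster$NT <= 1L) return(raster)
  states <- withr::with_seed(as.integer(seed), {
    perms <- lapply(seq_len(raster$n), function(i) sample.int(raster$NT))
    do.call(rbind, lapply(seq_len(raster$n), function(i) {
      raster$states[i, perms[[i]]]
    }))
  })
  binary_raster(states, raster$delta)
}

#' Write / read a raster as a 0/1 text matrix
#'
#' One time bin per line, nodes as space-separated columns, with a
#' `# delta` header line.
#'
#' @param raster a [binary_raster].
#' @param path file path.
#' @return `read_raster` returns a [binary_raster]; `write_raster` returns
#'   `path` invisibly.
#' @export
write_raster <- function(raster, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# delta %.17g", raster$delta), con)
  utils::write.table(t(raster$states), con, row.names = FALSE,
                     col.names = FALSE)
  invisible(path)
}

#' @rdname write_raster
#' @export
read_raster <- function(path) {
  lines <- readLines(path)
  delta <- as.numeric(sub("^# delta ", "",
                          grep("^# delta ", lines, value = TRUE)[1]))
  body <- lines[!startsWith(lines, "#") & nzchar(trimws(lines))]
  m <- do.call(rbind, lapply(strsplit(trimws(body), "\\s+"), as.integer))
  binary_raster(t(m), delta)
}
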