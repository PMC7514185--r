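#' Conditional-dependence statistic for one node pair
#'
#' For nodes `i`, `j` and a state `H` of the remaining nodes,
#' `Delta_ij(H) = |P(sigma_i = 1 | sigma_j = 1, H) -
#' P(sigma_i = 1 | sigma_j = 0, H)|`. It is zero for every `H` exactly
#' when `i` and `j` are conditionally independent given the rest.
#'
#' @param dist a [state_distribution].
#' @param i,j distinct node ids.
#' @param H state of the remaining `n - 2` nodes (0/1 vector ordered by
#'   node id, or state string).
#' @return the statistic, or `NA` when either conditioning event
#'   `(sigma_j = s, H)` has zero probability (an unsampled conditioning
#'   state is flagged, never silently zeroed).
#' @export
delta <- function(dist, i, j, H) {
  masks <- pair_condition_masks(dist$n, i, j, H)
  p <- dist$probs[masks + 1L]   # (si,sj) = (0,0),(1,0),(0,1),(1,1)
  d0 <- p[1L] + p[2L]
  d1 <- p[3L] + p[4L]
  if (d0 <= 0 || d1 <= 0) return(NA_real_)
  abs(p[4L] / d1 - p[2L] / d0)
}

#' Delta statistic over all conditioning states
#'
#' @param dist a [state_distribution].
#' @param i,j distinct node ids.
#' @return an object of class `delta_profile`: a data.frame with columns
#'   `H` (state string over the remaining nodes, ordered by node id) and
#'   `delta` (`NA` where undefined), one row per each of the `2^(n-2)`
#'   states, plus attributes `i`, `j`.
#' @export
delta_profile <- function(dist, i, j) {
  n <- dist$n
  stopifnot(n >= 2L)
  n_h <- 2L^(n - 2L)
  Hs <- if (n == 2L) "" else state_labels(n - 2L)
  vals <- vapply(seq_len(n_h), function(k) {
    H <- if (n == 2L) integer(0) else
      as.integer(strsplit(Hs[k], "")[[1]])
    delta(dist, i, j, H)
  }, numeric(1))
  structure(data.frame(H = Hs, delta = vals, stringsAsFactors = FALSE),
            i = as.integer(i), j = as.integer(j), class = c("delta_profile",
                                                            "data.frame"))
}

#' Shuffle-surrogate null for the Delta statistic and the interactions
#'
#' Generates `n_shuffles` independent surrogates of a raster by
#' per-node bin permutation ([shuffle_raster()]), recomputes the empirical
#' state distribution of each, and re-evaluates (a) the full
#' `Delta_ij(H)` profile for an optional node pair and (b) every
#' full-order effective interaction. The null band of a statistic is its
#' min-max envelope over the surrogates (mean and sd are also reported,
#' both for signed `J` and for `|J|`).
#'
#' @param raster a [binary_raster].
#' @param i,j optional node pair for the `Delta` profile (both or
#'   neither).
#' @param n_shuffles number of surrogates (default 10).
#' @param seed integer seed; surrogate `s` uses stream `seed + s - 1`.
#' @param pseudocount passed to [full_order_interactions()] for the
#'   surrogate distributions (default 0).
#' @return a list with elements
#'   `delta`: matrix `2^(n-2) x n_shuffles` of `Delta_ij(H)` values (row
#'   names are `H` strings), or `NULL` if no pair was given;
#'   `delta_summary`: per-`H` data.frame with `min`, `max`, `mean`, `sd`;
#'   `J`: matrix (subsets x shuffles) of signed interactions;
#'   `J_summary`: per-subset data.frame with signed `mean`/`sd` and
#'   absolute `min`/`max`/`mean`/`sd`;
#'   `moments1`: matrix (nodes x shuffles) of per-node activation
#'   fractions, identical across columns since permutation preserves
#'   per-node totals;
#'   `n_shuffles`, `seed`.
#' @export
shuffle_null <- function(raster, i = NULL, j = NULL, n_shuffles = 10L,
                         seed = 1L, pseudocount = 0) {
  stopifnot(inherits(raster, "binary_raster"), n_shuffles >= 1L)
  want_delta <- !is.null(i) && !is.null(j)
  n <- raster$n
  delta_mat <- NULL
  if (want_delta) delta_mat <- matrix(NA_real_, 2L^(n - 2L), n_shuffles)
  J_mat <- matrix(NA_real_, 2L^n, n_shuffles)
  m1 <- matrix(NA_real_, n, n_shuffles)
  for (s in seq_len(n_shuffles)) {
    sh <- shuffle_raster(raster, seed = as.integer(seed) + s - 1L)
    d <- empirical_distribution(sh)
    m1[, s] <- rowMeans(sh$states)
    if (want_delta) delta_mat[, s] <- delta_profile(d, i, j)$delta
    J_mat[, s] <- full_order_interactions(d, pseudocount = pseudocount)$J
  }
  sizes <- mask_sizes(n)
  keep <- sizes >= 1L
  subs <- vapply(which(keep) - 1L, function(mask) {
    paste(mask_to_subset(mask, n), collapse = ",")
  }, character(1))
  Jk <- J_mat[keep, , drop = FALSE]
  rownames(Jk) <- subs
  J_summary <- data.frame(
    subset = subs, order = sizes[keep],
    mean = rowMeans(Jk), sd = apply(Jk, 1L, stats::sd),
    abs_min = apply(abs(Jk), 1L, min), abs_max = apply(abs(Jk), 1L, max),
    abs_mean = rowMeans(abs(Jk)), abs_sd = apply(abs(Jk), 1L, stats::sd),
    stringsAsFactors = FALSE, row.names = NULL)
  delta_summary <- NULL
  if (want_delta) {
    rownames(delta_mat) <- if (n == 2L) "" else state_labels(n - 2L)
    delta_summary <- data.frame(
      H = rownames(delta_mat),
      min = apply(delta_mat, 1L, min, na.rm = TRUE),
      max = apply(delta_mat, 1L, max, na.rm = TRUE),
      mean = rowMeans(delta_mat, na.rm = TRUE),
      sd = apply(delta_mat, 1L, stats::sd, na.rm = TRUE),
      stringsAsFactors = FALSE, row.names = NULL)
  }
  list(delta = delta_mat, delta_summary = delta_summary,
       J = Jk, J_summary = J_summary, moments1 = m1,
       n_shuffles = as.integer(n_shuffles), seed = as.integer(seed))
}

#' Classify node pairs as structurally dependent or independent
#'
#' A pair `(i, j)` is predicted conditionally independent (given the
#' states of all other nodes) when `U_i` and `U_j` are disjoint, with
#' `U_i = C(i) + {i}`: the nodes are neither connected (in either
#' direction) nor share a common child. All other pairs are classified
#' dependent.
#'
#' @param graph a [coupling_graph].
#' @return a data.frame with columns `i`, `j` (`i < j`) and `status`
#'   (`"dependent"` or `"independent"`), one row per unordered pair.
#' @export
classify_pairs <- function(graph) {
  dep <- dependency_graph(graph)
  n <- graph$n
  pairs <- t(utils::combn(n, 2L))
  key <- paste(pairs[, 1L], pairs[, 2L])
  dep_key <- if (nrow(dep$dep_edges) > 0L) {
    paste(dep$dep_edges[, 1L], dep$dep_edges[, 2L])
  } else character(0)
  data.frame(i = pairs[, 1L], j = pairs[, 2L],
             status = ifelse(key %in% dep_key, "dependent", "independent"),
             stringsAsFactors = FALSE)
}

#' Write a Delta profile with its null band as JSON
#'
#' @param profile a [delta_profile()] result.
#' @param null optional [shuffle_null()] result for the same pair.
#' @param path file path.
#' @return `path`, invisibly.
#' @export
write_delta_profile <- function(profile, path, null = NULL) {
  rows <- lapply(seq_len(nrow(profile)), function(k) {
    r <- list(H = profile$H[k], delta = profile$delta[k])
    if (is.na(r$delta)) r$delta <- "undefined"
    if (!is.null(null)) {
      r$null_min <- null$delta_summary$min[k]
      r$null_max <- null$delta_summary$max[k]
      r$null_mean <- null$delta_summary$mean[k]
      r$null_sd <- null$delta_summary$sd[k]
    }
    r
  })
  jsonlite::write_json(list(i = attr(profile, "i"), j = attr(profile, "j"),
                            rows = rows),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
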