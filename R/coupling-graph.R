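#' Directed anatomical coupling graph
#'
#' Holds the directed connectivity of a pulse-coupled network: which node
#' sends pulses to which, whether each node is excitatory or inhibitory,
#' and the (dimensionless) conductance jump each connection delivers.
#'
#' @param n node count.
#' @param edges two-column integer matrix (or data.frame) of directed edges
#'   `(i, j)` meaning node `i` sends pulses to node `j`. No self-loops.
#' @param node_sign character vector of length `n`, each `"excitatory"` or
#'   `"inhibitory"` (abbreviations `"ex"`/`"in"` accepted).
#' @param strength either a single non-negative number applied to every
#'   edge, or a numeric vector with one entry per edge row.
#' @return an object of class `coupling_graph` with fields `n`, `edges`
#'   (integer matrix with columns `from`, `to`), `node_sign`, `strength`.
#' @examples
#' g <- coupling_graph(3, rbind(c(1, 3), c(2, 3)),
#'                     node_sign = c("ex", "ex", "in"), strength = 0.02)
#' @export
coupling_graph <- function(n, edges = NULL, node_sign = "excitatory",
                           strength = 0.02) {
  n <- as.integer(n)
  if (n < 1L) stop("n must be >= 1")
  if (is.null(edges) || NROW(edges) == 0L) {
    edges <- matrix(integer(0), ncol = 2L)
  }
  edges <- matrix(as.integer(as.matrix(edges)), ncol = 2L)
  colnames(edges) <- c("from", "to")
  if (any(edges < 1L) || any(edges > n)) stop("edge indices must lie in [1, n]")
  if (any(edges[, 1L] == edges[, 2L])) stop("self-loops are not allowed")
  if (anyDuplicated(edges)) stop("duplicate edges are not allowed")
  node_sign <- match.arg(rep(node_sign, length.out = n),
                         c("excitatory", "inhibitory"), several.ok = TRUE)
  strength <- rep(as.numeric(strength), length.out = nrow(edges))
  if (any(strength < 0)) stop("edge strengths must be >= 0")
  structure(list(n = n, edges = edges, node_sign = node_sign,
                 strength = strength),
            class = "coupling_graph")
}

#' @export
print.coupling_graph <- function(x, ...) {
  cat("coupling_graph:", x$n, "nodes,", nrow(x$edges), "directed edges\n")
  cat("  signs:", paste0(substr(x$node_sign, 1, 2), collapse = " "), "\n")
  if (nrow(x$edges) > 0L) {
    k <- min(10L, nrow(x$edges))
    cat("  edges:", paste(sprintf("%d->%d", x$edges[seq_len(k), 1L],
                                  x$edges[seq_len(k), 2L]), collapse = ", "),
        if (nrow(x$edges) > k) "..." else "", "\n")
  }
  invisible(x)
}

#' Child sets of every node
#'
#' @param graph a [coupling_graph].
#' @return a list of length `n`; element `i` is the integer vector `C(i)` of
#'   nodes that receive an edge from node `i`.
#' @export
children <- function(graph) {
  out <- rep(list(integer(0)), graph$n)
  if (nrow(graph$edges) > 0L) {
    sp <- split(graph$edges[, 2L], graph$edges[, 1L])
    out[as.integer(names(sp))] <- lapply(sp, function(v) sort(unique(v)))
  }
  out
}

#' Erdos-Renyi directed coupling graph
#'
#' Every ordered pair `(i, j)`, `i != j`, receives an edge independently
#' with probability `p` (a uniform draw on `[0, 1]` smaller than `p`).
#'
#' @param n node count.
#' @param p connection probability in `[0, 1]`.
#' @param seed integer seed; the draw is reproducible and does not disturb
#'   the global RNG state.
#' @param node_sign,strength passed to [coupling_graph()].
#' @return a [coupling_graph].
#' @export
er_graph <- function(n, p, seed, node_sign = "excitatory", strength = 0.02) {
  stopifnot(p >= 0, p <= 1)
  pairs <- cbind(rep(seq_len(n), each = n), rep(seq_len(n), times = n))
  pairs <- pairs[pairs[, 1L] != pairs[, 2L], , drop = FALSE]
  keep <- withr::with_seed(as.integer(seed),
                           stats::runif(nrow(pairs)) < p)
  coupling_graph(n, pairs[keep, , drop = FALSE],
                 node_sign = node_sign, strength = strength)
}

#' Write / read a coupling graph as an edge-list text file
#'
#' The format is a header block of `# node <i> <sign>` lines followed by one
#' `i j strength` line per directed edge; node ids are 1-based.
#'
#' @param graph a [coupling_graph].
#' @param path file path.
#' @return `read_coupling_graph` returns a [coupling_graph];
#'   `write_coupling_graph` returns `path` invisibly.
#' @export
write_coupling_graph <- function(graph, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# node %d %s", seq_len(graph$n), graph$node_sign), con)
  if (nrow(graph$edges) > 0L) {
    writeLines(sprintf("%d %d %.17g", graph$edges[, 1L], graph$edges[, 2L],
                       graph$strength), con)
  }
  invisible(path)
}

#' @rdname write_coupling_graph
#' @export
read_coupling_graph <- function(path) {
  lines <- readLines(path)
  hdr <- grep("^# node ", lines, value = TRUE)
  parts <- strsplit(trimws(sub("^# node ", "", hdr)), "\\s+")
  ids <- vapply(parts, function(p) as.integer(p[1]), integer(1))
  sign <- vapply(parts, function(p) p[2], character(1))[order(ids)]
  body <- lines[!startsWith(lines, "#") & nzchar(trimws(lines))]
  if (length(body) > 0L) {
    m <- do.call(rbind, strsplit(trimws(body), "\\s+"))
    edges <- cbind(as.integer(m[, 1L]), as.integer(m[, 2L]))
    strength <- as.numeric(m[, 3L])
  } else {
    edges <- NULL
    strength <- 0
  }
  coupling_graph(length(ids), edges, node_sign = sign, strength = strength)
}
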