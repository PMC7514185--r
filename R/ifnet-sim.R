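#' Parameters of the conductance-based integrate-and-fire model
#'
#' Each node carries a voltage-like state variable `x` obeying
#' `dx/dt = -x/tau - (g_bg + g_ex)(x - x_ex) - g_in(x - x_in)`.
#' Conductances jump instantaneously at input events (by `f` for background
#' Poisson arrivals, by the edge strength for recurrent spikes) and decay
#' exponentially with time scale `sigma_ex` (background and excitatory) or
#' `sigma_in` (inhibitory). When `x` reaches `x_th` the node fires, is
#' reset to `x_r` and clamped there for `tau_ref`.
#'
#' Defaults are the ring-network reference parameter set (see
#' [ring4_network()]).
#'
#' @param tau leak time constant (ms).
#' @param x_ex,x_in excitatory / inhibitory reversal values (dimensionless;
#'   must satisfy `x_in < x_r < x_th < x_ex`).
#' @param sigma_ex,sigma_in conductance decay time scales (ms).
#' @param x_th,x_r firing threshold and reset value.
#' @param tau_ref absolute refractory period (ms).
#' @param f background conductance jump magnitude (dimensionless).
#' @param mu background Poisson rate (events per ms).
#' @param dt integration step (ms).
#' @return an object of class `if_params` (a validated named list).
#' @export
if_params <- function(tau = 20, x_ex = 14 / 3, x_in = -2 / 3,
                      sigma_ex = 2, sigma_in = 5, x_th = 1, x_r = 0,
                      tau_ref = 2, f = 0.1, mu = 0.1, dt = 0.1) {
  p <- list(tau = tau, x_ex = x_ex, x_in = x_in, sigma_ex = sigma_ex,
            sigma_in = sigma_in, x_th = x_th, x_r = x_r, tau_ref = tau_ref,
            f = f, mu = mu, dt = dt)
  if (!all(vapply(p, function(v) is.numeric(v) && length(v) == 1L &&
                    is.finite(v), logical(1)))) {
    stop("all parameters must be finite scalars")
  }
  if (!(x_in < x_r && x_r < x_th && x_th < x_ex)) {
    stop("parameter ordering x_in < x_r < x_th < x_ex is violated")
  }
  if (tau <= 0 || sigma_ex <= 0 || sigma_in <= 0 || dt <= 0 || tau_ref <= 0) {
    stop("tau, sigma_ex, sigma_in, dt and tau_ref must be > 0")
  }
  if (mu < 0 || f < 0) stop("mu and f must be >= 0")
  structure(p, class = "if_params")
}

#' @export
print.if_params <- function(x, ...) {
  cat("if_params:\n")
  cat(sprintf("  tau=%g ms  x_th=%g  x_r=%g  x_ex=%g  x_in=%g\n",
              x$tau, x$x_th, x$x_r, x$x_ex, x$x_in))
  cat(sprintf("  sigma_ex=%g ms  sigma_in=%g ms  tau_ref=%g ms  dt=%g ms\n",
              x$sigma_ex, x$sigma_in, x$tau_ref, x$dt))
  cat(sprintf("  background: mu=%g /ms, jump f=%g\n", x$mu, x$f))
  invisible(x)
}

#' Construct a spike train set
#'
#' @param node integer vector of firing node ids (1-based).
#' @param time numeric vector of spike times in ms, within `[0, duration)`.
#' @param n node count.
#' @param duration total recording time (ms).
#' @return an object of class `spike_train_set` with fields `spikes` (a
#'   data.frame with columns `node`, `time`, sorted by time), `n`,
#'   `duration`.
#' @export
spike_train_set <- function(node, time, n, duration) {
  stopifnot(length(node) == length(time), duration > 0)
  if (length(time) > 0 && (min(time) < 0 || max(time) >= duration)) {
    stop("spike times must lie in [0, duration)")
  }
  ord <- order(time, node)
  structure(list(spikes = data.frame(node = as.integer(node)[ord],
                                     time = as.numeric(time)[ord]),
                 n = as.integer(n), duration = as.numeric(duration)),
            class = "spike_train_set")
}

#' @export
print.spike_train_set <- function(x, ...) {
  cat("spike_train_set:", nrow(x$spikes), "spikes from", x$n,
      "nodes over", x$duration, "ms\n")
  r <- firing_rates(x)
  cat("  rates (Hz):", paste(signif(r, 4), collapse = " "), "\n")
  invisible(x)
}

#' Per-node mean firing rates in Hz
#'
#' @param spikes a [spike_train_set].
#' @return numeric vector of length `n`: spikes per node divided by the
#'   recording time, converted from per-ms to Hz.
#' @export
firing_rates <- function(spikes) {
  counts <- tabulate(spikes$spikes$node, nbins = spikes$n)
  counts / spikes$duration * 1000
}

#' Simulate a pulse-coupled integrate-and-fire network
#'
#' Integrates the conductance-based dynamics (see [if_params()]) on a
#' directed [coupling_graph]. Background Poisson input uses one independent
#' RNG stream per node keyed by `(seed, node)`, so networks differing only
#' in their coupling share identical background realizations. All nodes
#' start at `x_r`; an initial transient is simulated and discarded before
#' recording so that the recorded segment is in statistical equilibrium.
#'
#' Voltage is advanced by second-order (midpoint) Runge-Kutta on
#' sub-intervals delimited by input events, with conductance decay applied
#' analytically; threshold crossings are located by linear interpolation
#' within a sub-interval. Spikes generated inside a step are delivered to
#' child nodes immediately after the step.
#'
#' @param graph a [coupling_graph].
#' @param params an [if_params] object.
#' @param duration recorded time (ms), after the transient.
#' @param seed integer seed for the background input streams. Identical
#'   `(graph, params, duration, seed)` reproduce the spike train
#'   bit-for-bit.
#' @param transient initial settling time (ms) discarded before recording.
#' @param background `"poisson"` for the stochastic background of the
#'   model, or `"constant"` to clamp `g_bg` at the fixed value `f`
#'   (deterministic drive, useful for closed-form checks).
#' @param check_bounds if `TRUE`, abort if any voltage leaves
#'   `[x_in, x_ex]` during integration (a debug assertion; the conductance
#'   form of the model guarantees the bound for exact dynamics).
#' @return a [spike_train_set].
#' @export
simulate_ifnet <- function(graph, params = if_params(), duration,
                           seed = 1L, transient = 1000,
                           background = c("poisson", "constant"),
                           check_bounds = FALSE) {
  stopifnot(inherits(graph, "coupling_graph"), inherits(params, "if_params"),
            duration > 0, transient >= 0)
  background <- match.arg(background)
  sign_num <- ifelse(graph$node_sign == "excitatory", 1L, -1L)
  res <- .cpp_simulate_ifnet(graph$n, graph$edges[, 1L], graph$edges[, 2L],
                             graph$strength, sign_num, unclass(params),
                             duration, transient, as.integer(seed),
                             background == "constant", check_bounds)
  spike_train_set(res$node, res$time, graph$n, duration)
}

#' Background Poisson event times for one node
#'
#' Homogeneous Poisson process on `[0, duration)` with rate `mu`, drawn
#' from the same deterministic per-node stream the simulator uses.
#'
#' @param mu event rate (per ms), `>= 0`.
#' @param duration interval length (ms).
#' @param seed integer seed.
#' @param node node id selecting the stream (default 1).
#' @return increasing numeric vector of event times.
#' @export
background_events <- function(mu, duration, seed, node = 1L) {
  stopifnot(mu >= 0, duration >= 0)
  as.numeric(.cpp_background_events(mu, duration, as.integer(seed),
                                    as.integer(node)))
}

#' Write / read spike trains as two-column text
#'
#' One `node_id time_ms` pair per line, time-sorted, with a `# duration`
#' and `# n` header.
#'
#' @param spikes a [spike_train_set].
#' @param path file path.
#' @return `read_spike_trains` returns a [spike_train_set];
#'   `write_spike_trains` returns `path` invisibly.
#' @export
write_spike_trains <- function(spikes, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(sprintf("# n %d", spikes$n),
               sprintf("# duration %.17g", spikes$duration)), con)
  if (nrow(spikes$spikes) > 0L) {
    writeLines(sprintf("%d %.17g", spikes$spikes$node, spikes$spikes$time),
               con)
  }
  invisible(path)
}

#' @rdname write_spike_trains
#' @export
read_spike_trains <- function(path) {
  lines <- readLines(path)
  n <- as.integer(sub("^# n ", "", grep("^# n ", lines, value = TRUE)[1]))
  duration <- as.numeric(sub("^# duration ", "",
                             grep("^# duration ", lines, value = TRUE)[1]))
  body <- lines[!startsWith(lines, "#") & nzchar(trimws(lines))]
  if (length(body) > 0L) {
    m <- do.call(rbind, strsplit(trimws(body), "\\s+"))
    spike_train_set(as.integer(m[, 1L]), as.numeric(m[, 2L]), n, duration)
  } else {
    spike_train_set(integer(0), numeric(0), n, duration)
  }
}
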