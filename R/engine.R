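# Pacing engine: periodic square-pulse stimulation of a cell model with an
# adaptive solver, uniform output sampling, and pacing to pseudo-steady state.

#' Pacing protocol
#'
#' Bundles the stimulation and solver settings for paced simulations.
#' Defaults follow standard safety-pharmacology practice: integration
#' tolerances of 1e-6 (absolute) and 1e-8 (relative), output sampled every
#' 0.1 ms, and steady state declared when the pace-to-pace L2 norm of the
#' state change drops below 1e-6.
#'
#' @param frequency Pacing frequency in Hz (> 0); the pace period is
#'   \code{1000/frequency} ms.
#' @param stim_amplitude Depolarising stimulus amplitude in uA/uF, or
#'   \code{NULL} to use the model's registered default.
#' @param stim_duration Pulse duration in ms (> 0).
#' @param stim_offset Pulse start, ms from the beginning of each pace.
#' @param abs_tol,rel_tol Solver tolerances.
#' @param output_step Output sampling interval in ms; must divide the pace
#'   period.
#' @param max_paces Pace limit for steady-state search; default is the
#'   smaller of 1800 paces and 5 simulated minutes at \code{frequency}.
#' @param steady_norm_tol Steady-state threshold on the pace-to-pace L2 norm
#'   of the state change.
#' @param method \code{"dopri"} (adaptive Dormand--Prince 5(4), default) or
#'   \code{"rk4"} (fixed-step 4th-order reference).
#' @param rk4_dt Fixed step in ms for \code{method = "rk4"}.
#' @return An object of class \code{ap_protocol}.
#' @export
#' @examples
#' pacing_protocol(frequency = 1)
pacing_protocol <- function(frequency = 1, stim_amplitude = NULL,
                            stim_duration = 2, stim_offset = 10,
                            abs_tol = 1e-6, rel_tol = 1e-8,
                            output_step = 0.1, max_paces = NULL,
                            steady_norm_tol = 1e-6,
                            method = c("dopri", "rk4"), rk4_dt = 0.001) {
  method <- match.arg(method)
  if (!is.numeric(frequency) || length(frequency) != 1L ||
      !is.finite(frequency) || frequency <= 0)
    stop("frequency must be a positive number of Hz", call. = FALSE)
  period <- 1000 / frequency
  if (!is.null(stim_amplitude) &&
      (!is.numeric(stim_amplitude) || !is.finite(stim_amplitude)))
    stop("stim_amplitude must be numeric", call. = FALSE)
  if (stim_duration <= 0) stop("stim_duration must be > 0", call. = FALSE)
  if (stim_offset < 0) stop("stim_offset must be >= 0", call. = FALSE)
  if (stim_offset + stim_duration >= period)
    stop("stimulus (offset + duration) must fit inside the pace period of ",
         period, " ms", call. = FALSE)
  if (output_step <= 0) stop("output_step must be > 0", call. = FALSE)
  n_steps <- period / output_step
  if (abs(n_steps - round(n_steps)) > 1e-6)
    stop("output_step must divide the pace period (", period, " ms)",
         call. = FALSE)
  if (abs_tol <= 0 || rel_tol <= 0)
    stop("tolerances must be positive", call. = FALSE)
  if (is.null(max_paces))
    max_paces <- min(1800L, as.integer(ceiling(300 * frequency)))
  max_paces <- as.integer(max_paces)
  if (max_paces < 1L) stop("max_paces must be >= 1", call. = FALSE)
  if (steady_norm_tol <= 0)
    stop("steady_norm_tol must be positive", call. = FALSE)
  structure(list(frequency = frequency, period = period,
                 stim_amplitude = stim_amplitude,
                 stim_duration = stim_duration, stim_offset = stim_offset,
                 abs_tol = abs_tol, rel_tol = rel_tol,
                 output_step = output_step, max_paces = max_paces,
                 steady_norm_tol = steady_norm_tol, method = method,
                 rk4_dt = rk4_dt),
            class = "ap_protocol")
}

#' @export
print.ap_protocol <- function(x, ...) {
  cat(sprintf("Pacing: %g Hz (period %g ms), stimulus %s uA/uF for %g ms at %g ms\n",
              x$frequency, x$period,
              if (is.null(x$stim_amplitude)) "model-default"
              else format(x$stim_amplitude),
              x$stim_duration, x$stim_offset))
  cat(sprintf("Solver: %s, abs_tol %g, rel_tol %g, output every %g ms\n",
              x$method, x$abs_tol, x$rel_tol, x$output_step))
  cat(sprintf("Steady state: L2 norm < %g, at most %d paces\n",
              x$steady_norm_tol, x$max_paces))
  invisible(x)
}

.resolve_stim <- function(model, protocol) {
  if (is.null(protocol$stim_amplitude))
    model$stimulus_defaults$amplitude
  else protocol$stim_amplitude
}

.new_trace <- function(times, voltages) {
  structure(list(times = times, voltages = voltages), class = "ap_trace")
}

#' @export
print.ap_trace <- function(x, ...) {
  cat(sprintf("AP trace: %d samples over %g ms, V in [%.2f, %.2f] mV\n",
              length(x$times), max(x$times), min(x$voltages),
              max(x$voltages)))
  invisible(x)
}

#' @export
as.data.frame.ap_trace <- function(x, ...) {
  data.frame(time_ms = x$times, V_mV = x$voltages)
}

#' @export
plot.ap_trace <- function(x, ...) {
  plot(x$times, x$voltages, type = "l", xlab = "time (ms)",
       ylab = "membrane voltage (mV)", ...)
  invisible(x)
}

#' Simulate a single pace
#'
#' Integrates the model over one pace period with the protocol's stimulus
#' pulse, returning the membrane voltage on the uniform output grid (via the
#' solver's dense output, not its internal steps) and the full ODE state at
#' the pace boundary.
#'
#' @param model An [get_model()] definition.
#' @param params Named parameter vector.
#' @param state Initial state vector.
#' @param protocol A [pacing_protocol()].
#' @return List with \code{trace} (class \code{ap_trace}) and
#'   \code{end_state}.
#' @export
#' @examples
#' m <- get_model("sixcurrent_demo")
#' p <- pacing_protocol(frequency = 1)
#' pace <- simulate_pace(m, m$default_parameters, m$default_initial_state, p)
#' range(pace$trace$voltages)
simulate_pace <- function(model, params = model$default_parameters, state,
                          protocol = pacing_protocol()) {
  stopifnot(inherits(model, "ap_cell_model"), inherits(protocol, "ap_protocol"))
  state <- as.numeric(state)
  bad <- which(!is.finite(state))
  if (length(bad) > 0L)
    stop("non-finite state value at index ", bad[1], call. = FALSE)
  res <- .cpp_simulate_pace(model$native, state,
                            .canonical_params(model, params),
                            protocol$period, .resolve_stim(model, protocol),
                            protocol$stim_duration, protocol$stim_offset,
                            protocol$abs_tol, protocol$rel_tol,
                            protocol$output_step, protocol$method,
                            protocol$rk4_dt)
  end_state <- res$end_state
  names(end_state) <- model$state_names
  list(trace = .new_trace(res$times, res$voltages), end_state = end_state)
}

#' Pace to pseudo-steady state
#'
#' Repeatedly applies [simulate_pace()] and, from the second pace onwards,
#' monitors the Euclidean (L2) norm of the raw state change between
#' consecutive pace ends.  Pacing stops when the norm falls below
#' \code{protocol$steady_norm_tol} (converged) or after
#' \code{protocol$max_paces}.  The final two voltage traces are retained so
#' that beat-to-beat alternans can be checked.
#'
#' @inheritParams simulate_pace
#' @param initial_state Starting state; defaults to the model's resting
#'   state.
#' @return An object of class \code{ap_steady}: \code{final_trace},
#'   \code{previous_trace} (NULL after a single pace), \code{end_state},
#'   \code{paces_run}, \code{converged}, \code{final_norm} and the full
#'   \code{norms} history.
#' @export
#' @examples
#' \donttest{
#' m <- get_model("sixcurrent_demo")
#' ss <- pace_to_steady(m, protocol = pacing_protocol(frequency = 1))
#' ss$converged
#' }
pace_to_steady <- function(model, params = model$default_parameters,
                           protocol = pacing_protocol(),
                           initial_state = model$default_initial_state) {
  stopifnot(inherits(model, "ap_cell_model"), inherits(protocol, "ap_protocol"))
  initial_state <- as.numeric(initial_state)
  res <- .cpp_pace_to_steady(model$native, initial_state,
                             .canonical_params(model, params),
                             protocol$period, .resolve_stim(model, protocol),
                             protocol$stim_duration, protocol$stim_offset,
                             protocol$abs_tol, protocol$rel_tol,
                             protocol$output_step, protocol$method,
                             protocol$rk4_dt, protocol$max_paces,
                             protocol$steady_norm_tol)
  end_state <- res$end_state
  names(end_state) <- model$state_names
  structure(list(
    final_trace = .new_trace(res$times, res$v_last),
    previous_trace = if (length(res$v_prev) > 0L)
      .new_trace(res$times, res$v_prev) else NULL,
    end_state = end_state,
    paces_run = res$paces_run,
    converged = res$converged,
    final_norm = res$final_norm,
    norms = res$norms
  ), class = "ap_steady")
}

#' @export
print.ap_steady <- function(x, ...) {
  cat(sprintf("Paced %d pace(s): %s (final pace-to-pace L2 norm %s)\n",
              x$paces_run,
              if (isTRUE(x$converged)) "converged" else "not converged",
              if (is.na(x$final_norm)) "n/a" else format(x$final_norm,
                                                         digits = 3)))
  invisible(x)
}

#' Write a voltage trace as CSV
#'
#' @param trace An \code{ap_trace}.
#' @param path Output file path.
#' @param step Optional resampling interval in ms (must be a multiple of the
#'   trace's own step); \code{NULL} writes the full grid.
#' @return \code{path}, invisibly.
#' @export
write_trace_csv <- function(trace, path, step = NULL) {
  stopifnot(inherits(trace, "ap_trace"))
  df <- as.data.frame(trace)
  if (!is.null(step)) {
    dt <- trace$times[2] - trace$times[1]
    by <- round(step / dt)
    if (by < 1 || abs(by * dt - step) > 1e-9)
      stop("step must be a multiple of the trace sampling interval",
           call. = FALSE)
    df <- df[seq(1, nrow(df), by = by), , drop = FALSE]
  }
  utils::write.csv(format_num_df(df), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

# fixed-format numbers so exports are byte-stable across locales/platforms
format_num_df <- function(df) {
  for (j in seq_along(df)) {
    if (is.numeric(df[[j]])) {
      s <- trimws(formatC(df[[j]], format = "g", digits = 10))
      s[is.na(df[[j]])] <- "NA"
      df[[j]] <- s
    }
  }
  df
}
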