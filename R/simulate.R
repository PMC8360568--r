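# Integration scales: absolute tolerances and steady-state checks are
# referenced to the resting magnitude of each state variable.
.STATE_SCALE <- c(v = 100, m = 1, h = 1, j = 1, hL = 1, d = 1, f = 1,
                  xr1 = 1, xs = 1, s = 1, y = 1, cai = 1e-3, casr = 1)

.model_dll <- function() "aprepair"

#' Pacing protocol
#'
#' Stimulation settings for paced single-cell simulations. Defaults follow
#' the common 1 Hz convention: cycle length 1000 ms with a 1 ms rectangular
#' stimulus whose amplitude (50 A/F) is about 1.5x the diastolic threshold
#' of the shipped surrogate model. Pacing runs for at most `n_prebeats`
#' beats, stopping early once the relative change of every state variable
#' between consecutive beat ends falls below `steady_tolerance`.
#'
#' @param cycle_length Pacing cycle length in ms.
#' @param stimulus_amplitude Depolarising stimulus amplitude in A/F.
#' @param stimulus_duration Stimulus duration in ms (< cycle length).
#' @param n_prebeats Maximum number of conditioning beats (>= 1).
#' @param steady_tolerance Relative per-state change between consecutive
#'   beats below which pacing is considered steady.
#' @param dt_output Uniform output grid step of the analysed beat (ms).
#' @return An object of class `pacing_protocol`.
#' @export
pacing_protocol <- function(cycle_length = 1000, stimulus_amplitude = 50,
                            stimulus_duration = 1, n_prebeats = 100,
                            steady_tolerance = 1e-3, dt_output = 0.05) {
  stopifnot(is.numeric(cycle_length), is.numeric(stimulus_amplitude),
            is.numeric(stimulus_duration), is.numeric(n_prebeats),
            is.numeric(steady_tolerance), is.numeric(dt_output))
  if (!(cycle_length > stimulus_duration && stimulus_duration > 0))
    stop("need cycle_length > stimulus_duration > 0", call. = FALSE)
  if (n_prebeats < 1) stop("'n_prebeats' must be >= 1", call. = FALSE)
  if (dt_output <= 0 || dt_output > cycle_length)
    stop("'dt_output' must be in (0, cycle_length]", call. = FALSE)
  structure(list(cycle_length = cycle_length,
                 stimulus_amplitude = stimulus_amplitude,
                 stimulus_duration = stimulus_duration,
                 n_prebeats = as.integer(n_prebeats),
                 steady_tolerance = steady_tolerance,
                 dt_output = dt_output),
            class = "pacing_protocol")
}

.integrate_beat <- function(y, times, parms, rtol, atol, with_currents = FALSE) {
  out <- try(deSolve::lsoda(
    y = y, times = times, func = "aprep_derivs", parms = parms,
    dllname = .model_dll(), initfunc = "aprep_initmod",
    nout = if (with_currents) length(.AP_CURRENTS) else 1,
    outnames = if (with_currents) .AP_CURRENTS else "aux",
    rtol = rtol, atol = atol, maxsteps = 100000), silent = TRUE)
  if (inherits(out, "try-error"))
    stop("integrator failure: ", attr(out, "condition")$message, call. = FALSE)
  istate <- attr(out, "istate")
  if (!is.null(istate) && istate[1] < 0)
    stop(sprintf("integrator failure (istate = %d) near t = %.3f ms",
                 istate[1], out[nrow(out), 1]), call. = FALSE)
  if (any(!is.finite(out[, 1 + seq_along(.AP_STATES)]))) {
    bad <- which(!stats::complete.cases(out[, 1 + seq_along(.AP_STATES)]))[1]
    stop(sprintf("integrator failure: non-finite state near t = %.3f ms",
                 out[bad, 1]), call. = FALSE)
  }
  out
}

#' Simulate a paced beat of an action-potential model
#'
#' Integrates the model ODEs (stiff adaptive solver, relative tolerance
#' `rtol`, per-state absolute tolerances scaled to resting magnitudes) with
#' each membrane current scaled by its drug combination factor. The model is
#' paced from `init` for up to `n_prebeats` conditioning beats -- stopping
#' early at the protocol's steady tolerance -- and the final beat is
#' returned on a uniform output grid. With all factors equal to 1 this is
#' exactly the drug-free model (identical code path).
#'
#' @param model An [build_ap_model()] object.
#' @param factors Optional named per-current scale factors (from
#'   [model_factors()] or [combined_factor()]); all >= 0.
#' @param protocol A [pacing_protocol()].
#' @param init Optional named initial state; defaults to the model file's
#'   resting state. Pass the final state of a previous run (attribute
#'   `final_state`) to continue from a paced steady state.
#' @param include_currents If `TRUE`, the returned trace carries one column
#'   per membrane current (A/F).
#' @param rtol Relative integration tolerance.
#' @return An `ap_trace`: a data.frame with columns `time` (ms), `v` (mV),
#'   `ca` (cytosolic Ca2+, uM) and optionally the currents, with attributes
#'   `final_state`, `n_beats`, `steady` and the protocol.
#' @export
simulate_ap <- function(model, factors = NULL, protocol = pacing_protocol(),
                        init = NULL, include_currents = FALSE, rtol = 1e-6) {
  stopifnot(inherits(model, "ap_model"), inherits(protocol, "pacing_protocol"))
  parms <- model_parms(model, factors, protocol)
  y <- if (is.null(init)) model$initial_state else init[.AP_STATES]
  if (any(is.na(y))) stop("'init' must name all state variables", call. = FALSE)
  y <- unlist(y)
  atol <- rtol * .STATE_SCALE
  cl <- protocol$cycle_length

  steady <- FALSE
  n_run <- 0L
  if (protocol$n_prebeats > 1L) {
    for (b in seq_len(protocol$n_prebeats - 1L)) {
      out <- .integrate_beat(y, c(0, cl), parms, rtol, atol)
      y_new <- out[nrow(out), 1 + seq_along(.AP_STATES)]
      names(y_new) <- .AP_STATES
      n_run <- n_run + 1L
      rel <- max(abs(y_new - y) / pmax(abs(y), .STATE_SCALE * 1e-3))
      y <- y_new
      if (rel < protocol$steady_tolerance) { steady <- TRUE; break }
    }
  }

  times <- seq(0, cl, by = protocol$dt_output)
  out <- .integrate_beat(y, times, parms, rtol, atol, with_currents = include_currents)
  n_run <- n_run + 1L
  final_state <- out[nrow(out), 1 + seq_along(.AP_STATES)]
  names(final_state) <- .AP_STATES

  tr <- data.frame(time = out[, "time"], v = out[, "v"],
                   ca = out[, "cai"] * 1000)  # mM -> uM
  if (include_currents)
    tr <- cbind(tr, as.data.frame(out[, .AP_CURRENTS, drop = FALSE]))
  structure(tr,
            class = c("ap_trace", "data.frame"),
            final_state = final_state,
            n_beats = n_run,
            steady = steady,
            protocol = protocol,
            cell_type = model$cell_type,
            mutation = model$mutation)
}

#' @export
print.ap_trace <- function(x, ...) {
  pr <- attr(x, "protocol")
  cat(sprintf("<ap_trace> %s %s | %d points, %.0f ms | beats run: %d%s\n",
              attr(x, "cell_type") %||% "?", attr(x, "mutation") %||% "",
              nrow(x), max(x$time), attr(x, "n_beats") %||% NA,
              if (isTRUE(attr(x, "steady"))) " (steady)" else ""))
  invisible(x)
}

#' Export a trace to delimited text
#'
#' Writes tab-separated columns `time_ms`, `v_mV`, `ca_uM` and one column
#' per stored current, with a mandatory header row.
#'
#' @param trace An `ap_trace`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_trace <- function(trace, path) {
  stopifnot(inherits(trace, "ap_trace"))
  df <- as.data.frame(trace)
  names(df)[names(df) == "time"] <- "time_ms"
  names(df)[names(df) == "v"] <- "v_mV"
  names(df)[names(df) == "ca"] <- "ca_uM"
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a trace written by [write_trace()]
#'
#' @param path File path.
#' @return An `ap_trace` data.frame (time in ms, v in mV, ca in uM).
#' @export
read_trace <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE)
  if (!all(c("time_ms", "v_mV", "ca_uM") %in% names(df)))
    stop("not a trace file (need time_ms, v_mV, ca_uM columns): ", path,
         call. = FALSE)
  names(df)[match(c("time_ms", "v_mV", "ca_uM"), names(df))] <- c("time", "v", "ca")
  structure(df, class = c("ap_trace", "data.frame"))
}
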