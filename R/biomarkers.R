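.APD_LEVELS <- seq(10, 90, by = 10)
.CAD_LEVELS <- c(30, 50, 80)

#' Names of the biomarker panel
#'
#' The full panel extracted from a paced beat: resting membrane potential
#' (RMP, mV), action-potential amplitude (APA, mV), maximal upstroke
#' velocity (dvdt_max, mV/ms), action-potential durations at 10..90%
#' repolarization (APD10..APD90, ms), resting cytosolic calcium (CaR, uM),
#' calcium transient amplitude (CaA, uM), maximal calcium upstroke
#' (dcdt_max, uM/ms) and calcium transient durations (CaD30/50/80, ms).
#'
#' @return Character vector of biomarker names.
#' @export
biomarker_names <- function() {
  c("RMP", "APA", "dvdt_max", paste0("APD", .APD_LEVELS),
    "CaR", "CaA", "dcdt_max", paste0("CaD", .CAD_LEVELS))
}

# Durations of one transient: from the instant of maximal upstroke velocity
# to the first later downward crossing of peak - level% of amplitude,
# linearly interpolated between grid points. Censored durations (threshold
# never re-crossed) are reported at the beat end and flagged.
.transient_markers <- function(t, x, levels, t_search_from) {
  i0 <- which(t >= t_search_from)[1]
  dx <- diff(x) / diff(t)
  # maximal upstroke after the stimulus, by central differences on the
  # uniform grid (forward differences at the edges)
  n <- length(x)
  slope <- c(dx[1], (x[-(1:2)] - x[1:(n - 2)]) / (t[-(1:2)] - t[1:(n - 2)]), dx[n - 1])
  search <- seq(i0, n)
  i_up <- search[which.max(slope[search])]
  i_peak <- which.max(x[i_up:n]) + i_up - 1L
  rest <- x[1]
  peak <- x[i_peak]
  amp <- peak - rest
  dur <- numeric(length(levels))
  censored <- logical(length(levels))
  for (k in seq_along(levels)) {
    thr <- peak - levels[k] / 100 * amp
    below <- which(x < thr)
    below <- below[below > i_peak]
    if (!length(below)) {
      dur[k] <- t[n] - t[i_up]
      censored[k] <- TRUE
    } else {
      i <- below[1]
      # linear interpolation of the downward crossing between i-1 and i
      tc <- t[i - 1] + (thr - x[i - 1]) / (x[i] - x[i - 1]) * (t[i] - t[i - 1])
      dur[k] <- tc - t[i_up]
    }
  }
  list(rest = rest, peak = peak, amp = amp, dvdt_max = max(slope[search]),
       t_up = t[i_up], dur = dur, censored = censored)
}

#' Extract the biomarker panel from a paced-beat trace
#'
#' Conventions: RMP and CaR are the values at stimulus onset (the first
#' sample of the beat); APA and CaA are peak minus rest; upstroke
#' velocities are maximal central-difference slopes with the search started
#' at the end of the stimulus (so the stimulus artifact is excluded);
#' durations run from the instant of maximal upstroke velocity to the first
#' subsequent downward crossing of `peak - (p/100) * amplitude`, linearly
#' interpolated between grid points. By default calcium durations use the
#' same decay-from-peak convention as the APDs (`ca_duration = "decay"`);
#' `"width"` instead measures the width of the transient at p% of its
#' amplitude above rest (crossing level `rest + (p/100) * amplitude`,
#' measured from the same upstroke instant).
#'
#' A duration whose threshold is never re-crossed within the beat is
#' reported at the beat end and flagged in the `censored` attribute.
#'
#' @param trace An `ap_trace` (columns `time`, `v`, `ca`) covering one beat.
#' @param ca_duration `"decay"` (default) or `"width"`; see Details.
#' @return Named numeric vector of class `biomarker_set` with attribute
#'   `censored` (character vector of censored biomarker names).
#' @export
compute_biomarkers <- function(trace, ca_duration = c("decay", "width")) {
  ca_duration <- match.arg(ca_duration)
  stopifnot(is.data.frame(trace), all(c("time", "v", "ca") %in% names(trace)))
  t <- trace$time; v <- trace$v; ca <- trace$ca
  if (length(t) < 5 || any(diff(t) <= 0))
    stop("trace 'time' must be strictly increasing with >= 5 samples", call. = FALSE)
  if (any(!is.finite(v)) || any(!is.finite(ca)))
    stop("trace contains non-finite values", call. = FALSE)
  if (diff(range(v)) <= 20)
    stop("no AP detected: voltage range <= 20 mV", call. = FALSE)
  proto <- attr(trace, "protocol")
  stim_end <- if (!is.null(proto)) proto$stimulus_duration else 0

  vm <- .transient_markers(t, v, .APD_LEVELS, stim_end)
  cm <- .transient_markers(t, ca, .CAD_LEVELS, stim_end)
  cad <- cm$dur
  cad_cens <- cm$censored
  if (ca_duration == "width") {
    for (k in seq_along(.CAD_LEVELS)) {
      thr <- cm$rest + .CAD_LEVELS[k] / 100 * cm$amp
      i_peak <- which.max(ca)
      below <- which(ca < thr)
      below <- below[below > i_peak]
      if (!length(below)) {
        cad[k] <- t[length(t)] - cm$t_up
        cad_cens[k] <- TRUE
      } else {
        i <- below[1]
        tc <- t[i - 1] + (thr - ca[i - 1]) / (ca[i] - ca[i - 1]) * (t[i] - t[i - 1])
        cad[k] <- tc - cm$t_up
        cad_cens[k] <- FALSE
      }
    }
  }

  out <- c(vm$rest, vm$amp, vm$dvdt_max, vm$dur,
           cm$rest, cm$amp, cm$dvdt_max, cad)
  names(out) <- biomarker_names()
  cens <- c(paste0("APD", .APD_LEVELS)[vm$censored],
            paste0("CaD", .CAD_LEVELS)[cad_cens])
  structure(out, class = "biomarker_set", censored = cens)
}

#' @export
print.biomarker_set <- function(x, ...) {
  units <- c(RMP = "mV", APA = "mV", dvdt_max = "mV/ms",
             stats::setNames(rep("ms", 9), paste0("APD", .APD_LEVELS)),
             CaR = "uM", CaA = "uM", dcdt_max = "uM/ms",
             stats::setNames(rep("ms", 3), paste0("CaD", .CAD_LEVELS)))
  cens <- attr(x, "censored")
  for (nm in names(x))
    cat(sprintf("%-9s %10.4g %-6s%s\n", nm, x[[nm]], units[[nm]],
                if (nm %in% cens) " [censored]" else ""))
  invisible(x)
}

#' Write a biomarker report to delimited text
#'
#' One row per biomarker with columns `biomarker`, `value`, `units`,
#' `censored`.
#'
#' @param biomarkers A `biomarker_set`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_biomarkers <- function(biomarkers, path) {
  stopifnot(inherits(biomarkers, "biomarker_set"))
  units <- c(rep("mV", 2), "mV/ms", rep("ms", 9), rep("uM", 2), "uM/ms",
             rep("ms", 3))
  df <- data.frame(biomarker = names(biomarkers),
                   value = as.numeric(biomarkers),
                   units = units,
                   censored = names(biomarkers) %in% attr(biomarkers, "censored"))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Synthetic trace with analytically known biomarkers
#'
#' Generates a stylised beat for testing the biomarker extractor: the
#' voltage rests at `rest`, rises to `rest + amplitude` over `ramp_ms`
#' along a half-cosine (so the maximal upstroke velocity
#' `amplitude * pi / (2 * ramp_ms)` occurs at the unique instant
#' `ramp_ms / 2`), then returns to rest either linearly over `decay_ms`
#' (`decay = "linear"`) or exponentially with time constant `tau_ms`
#' (`decay = "exponential"`). The calcium channel of the trace follows the
#' same shape scaled into concentration units (rest `ca_rest`, amplitude
#' `ca_amplitude`). The analytic biomarker panel implied by the geometry
#' (durations measured from the maximal-upstroke instant) is attached as
#' attribute `analytic`.
#'
#' @param rest Resting potential (mV).
#' @param amplitude AP amplitude (mV, > 0).
#' @param ramp_ms Upstroke duration (ms, > 0).
#' @param decay `"linear"` or `"exponential"`.
#' @param decay_ms Linear return-to-rest duration (ms).
#' @param tau_ms Exponential decay time constant (ms).
#' @param beat_ms Total beat length (ms).
#' @param dt Output grid step (ms).
#' @param ca_rest,ca_amplitude Calcium rest level and amplitude (uM).
#' @return An `ap_trace` with attribute `analytic` (a `biomarker_set`).
#' @export
synth_trace <- function(rest = -80, amplitude = 120, ramp_ms = 2,
                        decay = c("linear", "exponential"),
                        decay_ms = 300, tau_ms = 100, beat_ms = 1000,
                        dt = 0.05, ca_rest = 0.1, ca_amplitude = 1) {
  decay <- match.arg(decay)
  if (amplitude <= 0 || ca_amplitude <= 0) stop("amplitudes must be > 0", call. = FALSE)
  if (ramp_ms <= 0 || beat_ms <= ramp_ms) stop("need beat_ms > ramp_ms > 0", call. = FALSE)
  if (decay == "linear" && (decay_ms <= 0 || ramp_ms + decay_ms > beat_ms))
    stop("need ramp_ms + decay_ms <= beat_ms", call. = FALSE)
  if (decay == "exponential" && tau_ms <= 0) stop("'tau_ms' must be > 0", call. = FALSE)

  t <- seq(0, beat_ms, by = dt)
  shape <- function(tt) {
    up <- ifelse(tt <= 0, 0,
                 ifelse(tt >= ramp_ms, 1, (1 - cos(pi * tt / ramp_ms)) / 2))
    dn <- if (decay == "linear")
      pmin(pmax((tt - ramp_ms) / decay_ms, 0), 1)
    else
      ifelse(tt > ramp_ms, 1 - exp(-(tt - ramp_ms) / tau_ms), 0)
    up - dn  # in [0, 1]: 1 at full depolarization, 0 at rest
  }
  s <- shape(t)
  v <- rest + amplitude * s
  ca <- ca_rest + ca_amplitude * s

  # analytic panel: maximal upstroke velocity amplitude*pi/(2*ramp_ms) at
  # t = ramp_ms/2; durations run from that instant to the decay crossing of
  # peak - p% * amplitude (the decay starts at the ramp top, t = ramp_ms)
  lv <- .APD_LEVELS
  t_up <- ramp_ms / 2
  dur <- if (decay == "linear") ramp_ms - t_up + decay_ms * lv / 100
         else ramp_ms - t_up + tau_ms * log(100 / (100 - lv))
  cad <- if (decay == "linear") ramp_ms - t_up + decay_ms * .CAD_LEVELS / 100
         else ramp_ms - t_up + tau_ms * log(100 / (100 - .CAD_LEVELS))
  vel <- pi / 2 / ramp_ms
  analytic <- c(rest, amplitude, amplitude * vel, dur,
                ca_rest, ca_amplitude, ca_amplitude * vel, cad)
  names(analytic) <- biomarker_names()
  structure(data.frame(time = t, v = v, ca = ca),
            class = c("ap_trace", "data.frame"),
            analytic = structure(analytic, class = "biomarker_set",
                                 censored = character(0)))
}
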