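#' Steady state of the I_Kr inactivation gate
#'
#' Voltage dependence of the steady-state value of the rapid delayed
#' rectifier inactivation gate (xKr2). For the wild-type channel
#' `1 / (1 + exp((v + 70) / 20.9))`; the SQT1 N588K gain-of-function variant
#' shifts the midpoint by +62 mV and scales the slope factor by 1.85:
#' `1 / (1 + exp((v + 70 - 62) / (20.9 * 1.85)))`. The mutant curve lies
#' above the wild-type curve over the physiological voltage range, so mutant
#' channels inactivate far less at depolarised potentials -- the mechanistic
#' origin of the enlarged I_Kr and the shortened action potential.
#'
#' @param v Membrane potential(s) in mV; must be finite.
#' @param variant `"WT"` or `"N588K"`.
#' @return Steady-state open fraction(s) of the inactivation gate in `[0, 1]`.
#' @examples
#' xkr2_inf(-70, "WT")     # midpoint: 0.5
#' xkr2_inf(-8, "N588K")   # shifted midpoint: 0.5
#' @export
xkr2_inf <- function(v, variant = c("WT", "N588K")) {
  variant <- match.arg(variant)
  if (!is.numeric(v) || any(!is.finite(v)))
    stop("'v' must be finite (mV)", call. = FALSE)
  if (variant == "WT") 1 / (1 + exp((v + 70) / 20.9))
  else                 1 / (1 + exp((v + 70 - 62) / (20.9 * 1.85)))
}
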