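#' Hill-type drug effect on a single ion current
#'
#' Constructs the parameter triple of the sigmoidal (EC50/IC50) dose-effect
#' relationship used throughout the package. A drug at dose `D` (uM) scales a
#' current `I` as `I(D) = (1 + eta(D)) * I(0)` with
#' `eta(D) = (eps*D)^H / ((eps*D)^H + 1) * E`, where `eps = 1/EC50`.
#'
#' @param ec50 Half-maximal concentration in uM (must be > 0).
#' @param hill Hill coefficient, dimensionless (> 0).
#' @param emax Maximum relative effect `E` at saturating dose. `emax = -1` is a
#'   complete block (the classical IC50 model); positive values describe
#'   agonists. A value below -1 would drive the current negative and is
#'   rejected; `emax = 0` would be a null effect and is also rejected.
#' @param source Optional free-text provenance note.
#' @return An object of class `hill_effect`.
#' @examples
#' h <- hill_effect(ec50 = 15.77, hill = 0.6, emax = -1)
#' eta(h, 15.77)  # half-maximal: -0.5
#' @export
hill_effect <- function(ec50, hill, emax, source = NULL) {
  stopifnot(is.numeric(ec50), length(ec50) == 1L, is.finite(ec50),
            is.numeric(hill), length(hill) == 1L, is.finite(hill),
            is.numeric(emax), length(emax) == 1L, is.finite(emax))
  if (ec50 <= 0) stop("'ec50' must be > 0 (uM)", call. = FALSE)
  if (hill <= 0) stop("'hill' must be > 0", call. = FALSE)
  if (emax < -1) stop("'emax' must be >= -1: a current cannot be blocked by more than 100%",
                      call. = FALSE)
  if (emax == 0) stop("'emax' must be nonzero", call. = FALSE)
  structure(list(eps = 1 / as.numeric(ec50), hill = as.numeric(hill),
                 emax = as.numeric(emax),
                 source = if (is.null(source)) NA_character_ else as.character(source)),
            class = "hill_effect")
}

#' @export
print.hill_effect <- function(x, ...) {
  cat(sprintf("<hill_effect> EC50 = %g uM, H = %g, E = %+g\n",
              1 / x$eps, x$hill, x$emax))
  invisible(x)
}

# (eps*D)^H via exp(H*log(eps*D)); exact 0 at D = 0 so non-integer H never
# sees log(0).
.hill_pow <- function(eps, hill, dose) {
  out <- numeric(length(dose))
  pos <- dose > 0
  out[pos] <- exp(hill * log(eps * dose[pos]))
  out
}

.check_dose <- function(dose) {
  if (!is.numeric(dose) || any(!is.finite(dose)))
    stop("doses must be finite numbers (uM)", call. = FALSE)
  if (any(dose < 0)) stop("doses must be >= 0 (uM)", call. = FALSE)
  invisible(dose)
}

#' Relative change of a current under a drug dose
#'
#' `eta(D) = (eps*D)^H / ((eps*D)^H + 1) * E`: the fractional change of the
#' current, so the scaled current is `(1 + eta) * I(0)`. `eta(0) = 0`,
#' `eta(EC50) = E/2` and `eta(Inf) = E`.
#'
#' @param effect A [hill_effect()].
#' @param dose Dose(s) in uM, each >= 0. Vectorised.
#' @return Numeric vector of relative changes (dimensionless).
#' @export
eta <- function(effect, dose) {
  stopifnot(inherits(effect, "hill_effect"))
  .check_dose(dose)
  x <- .hill_pow(effect$eps, effect$hill, dose)
  x / (x + 1) * effect$emax
}

#' Fraction of the maximum drug effect reached at a dose
#'
#' The saturation fraction `(eps*D)^H / ((eps*D)^H + 1) = eta(D)/E`, in
#' `[0, 1)`. Reported in dose tables as "max % of E" for the current most
#' strongly affected by a drug.
#'
#' @inheritParams eta
#' @return Numeric vector in `[0, 1)`.
#' @export
saturation_fraction <- function(effect, dose) {
  stopifnot(inherits(effect, "hill_effect"))
  .check_dose(dose)
  x <- .hill_pow(effect$eps, effect$hill, dose)
  x / (x + 1)
}

#' Per-current drug profile
#'
#' Bundles the [hill_effect()] entries of one drug, keyed by ion-current
#' label (e.g. `"I_Kr"`, `"I_CaL"`). A current with no entry is unaffected by
#' the drug (combination factor 1).
#'
#' @param name Drug name.
#' @param effects Named list of [hill_effect()] objects; names are current
#'   labels. At least one entry is required.
#' @return An object of class `drug_profile`.
#' @export
drug_profile <- function(name, effects) {
  stopifnot(is.character(name), length(name) == 1L, nzchar(name))
  if (!is.list(effects) || length(effects) == 0L || is.null(names(effects)) ||
      any(!nzchar(names(effects))))
    stop("'effects' must be a non-empty named list of hill_effect objects",
         call. = FALSE)
  ok <- vapply(effects, inherits, logical(1), what = "hill_effect")
  if (!all(ok)) stop("all entries of 'effects' must be hill_effect objects", call. = FALSE)
  if (anyDuplicated(names(effects)))
    stop("duplicated current labels in 'effects'", call. = FALSE)
  structure(list(name = name, effects = effects), class = "drug_profile")
}

#' @export
print.drug_profile <- function(x, ...) {
  cat(sprintf("<drug_profile> %s (%d current%s)\n", x$name, length(x$effects),
              if (length(x$effects) == 1L) "" else "s"))
  for (cur in names(x$effects)) {
    e <- x$effects[[cur]]
    cat(sprintf("  %-6s EC50 = %g uM, H = %g, E = %+g\n", cur, 1 / e$eps, e$hill, e$emax))
  }
  invisible(x)
}

#' Validate a dose vector against a set of drug profiles
#'
#' @param doses Named numeric vector, drug name -> concentration (uM, >= 0).
#' @param profiles Named list of [drug_profile()] objects.
#' @return The dose vector, invisibly, after validation.
#' @export
dose_vector <- function(doses, profiles = NULL) {
  if (length(doses) && (is.null(names(doses)) || any(!nzchar(names(doses)))))
    stop("'doses' must be a named numeric vector (drug -> uM)", call. = FALSE)
  .check_dose(doses)
  if (anyDuplicated(names(doses))) stop("duplicated drug names in 'doses'", call. = FALSE)
  if (!is.null(profiles)) {
    unknown <- setdiff(names(doses), names(profiles))
    if (length(unknown))
      stop("dose given for unknown drug(s): ", paste(unknown, collapse = ", "),
           call. = FALSE)
  }
  invisible(doses)
}

#' Multiplicative combination factor for one current
#'
#' The scale factor applied to current `current_id` when several drugs act
#' simultaneously: the product over dosed drugs of `(1 + eta_k(D_k))`. Drugs
#' with no effect entry for the current contribute a factor of 1. The
#' multiplicative form assumes strictly independent (non-interacting)
#' binding of the drugs to the channel.
#'
#' @param profiles Named list of [drug_profile()] objects (names are drug
#'   names; unnamed lists are keyed by each profile's own name).
#' @param doses Named numeric vector, drug name -> dose in uM. Every dosed
#'   drug must have a profile.
#' @param current_id Ion-current label, e.g. `"I_Kr"`.
#' @return A single positive scale factor.
#' @export
combined_factor <- function(profiles, doses, current_id) {
  profiles <- as_profile_list(profiles)
  dose_vector(doses, profiles)
  stopifnot(is.character(current_id), length(current_id) == 1L)
  f <- 1
  for (drug in names(doses)) {
    e <- profiles[[drug]]$effects[[current_id]]
    if (!is.null(e)) f <- f * (1 + eta(e, doses[[drug]]))
  }
  f
}

# Accept either a named list of profiles or an unnamed list/single profile;
# always return a list keyed by drug name.
as_profile_list <- function(profiles) {
  if (inherits(profiles, "drug_profile")) profiles <- list(profiles)
  if (!is.list(profiles) || !all(vapply(profiles, inherits, logical(1), "drug_profile")))
    stop("'profiles' must be drug_profile objects", call. = FALSE)
  nm <- vapply(profiles, `[[`, character(1), "name")
  if (anyDuplicated(nm)) stop("duplicated drug profiles: ",
                              paste(nm[duplicated(nm)], collapse = ", "), call. = FALSE)
  names(profiles) <- nm
  profiles
}

#' Percent change of each current under a dose combination
#'
#' Tabulates `100 * (F_i - 1)` for the multiplicative combination factor
#' `F_i` of each requested current. Values are exact; presentation rounding
#' (one decimal, half away from zero, as in published dose tables) is applied
#' by `print()` only.
#'
#' @inheritParams combined_factor
#' @param currents Character vector of current labels. Defaults to the union
#'   of currents named by the dosed drugs' profiles.
#' @return A data.frame with columns `current` and `percent_change`, class
#'   `percent_change_table`.
#' @export
percent_change_table <- function(profiles, doses,
                                 currents = NULL) {
  profiles <- as_profile_list(profiles)
  dose_vector(doses, profiles)
  if (is.null(currents)) {
    currents <- unique(unlist(lapply(profiles[names(doses)],
                                     function(p) names(p$effects))))
    if (is.null(currents)) currents <- character(0)
  }
  pc <- vapply(currents, function(cur)
    100 * (combined_factor(profiles, doses, cur) - 1), numeric(1))
  structure(data.frame(current = currents, percent_change = unname(pc),
                       stringsAsFactors = FALSE),
            class = c("percent_change_table", "data.frame"))
}

#' @export
print.percent_change_table <- function(x, ...) {
  y <- data.frame(current = x$current,
                  percent_change = sprintf("%+.1f%%", round_half_away(x$percent_change, 1)))
  print.data.frame(y, row.names = FALSE)
  invisible(x)
}
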