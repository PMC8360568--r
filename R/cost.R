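#' Biomarker weights of the repair cost function
#'
#' The cost of a dose vector is the weighted sum of relative absolute
#' biomarker deviations between the drug-treated mutant and the wild type:
#' `C(D) = sum_j w_j * |R_j^M(D) - R_j^W| / |R_j^W|`. By default every
#' biomarker has weight 1 except APD80, APD90 and dvdt_max, which are
#' weighted 5 (late repolarization and upstroke velocity dominate the
#' arrhythmogenic phenotype).
#'
#' @param weights Optional named numeric vector overriding individual
#'   default weights; names must be biomarkers from [biomarker_names()].
#' @return Named weight vector of class `cost_spec`.
#' @export
cost_spec <- function(weights = NULL) {
  w <- stats::setNames(rep(1, length(biomarker_names())), biomarker_names())
  w[c("APD80", "APD90", "dvdt_max")] <- 5
  if (!is.null(weights)) {
    if (is.null(names(weights)) || !all(names(weights) %in% biomarker_names()))
      stop("'weights' must be named by biomarkers from biomarker_names()",
           call. = FALSE)
    w[names(weights)] <- weights
  }
  if (any(w < 0) || all(w == 0))
    stop("weights must be >= 0 with at least one > 0", call. = FALSE)
  structure(w, class = "cost_spec")
}

#' Weighted biomarker distance between two biomarker sets
#'
#' @param treated,reference `biomarker_set` (or named) vectors.
#' @param spec A [cost_spec()].
#' @return Nonnegative scalar; 0 iff all weighted biomarkers coincide.
#' @export
biomarker_distance <- function(treated, reference, spec = cost_spec()) {
  nm <- names(unclass(spec))
  active <- nm[unclass(spec)[nm] > 0]
  if (any(!is.finite(reference[active])) || any(reference[active] == 0))
    stop("reference biomarkers must be nonzero for all weighted terms",
         call. = FALSE)
  sum(unclass(spec)[active] * abs(treated[active] - reference[active]) /
        abs(reference[active]))
}

#' Generic cost-landscape context for the dose optimizers
#'
#' Wraps an arbitrary objective `fn(doses)` (named dose vector, uM ->
#' nonnegative scalar) so the optimizers in this package can be exercised
#' and validated on cheap analytic landscapes.
#'
#' @param fn Objective function taking a named dose vector.
#' @param profiles Optional drug profiles (used only for low-dose
#'   tie-breaking).
#' @return An object of class `cost_context`.
#' @export
objective_context <- function(fn, profiles = NULL) {
  stopifnot(is.function(fn))
  structure(list(objective = fn,
                 profiles = if (is.null(profiles)) NULL else as_profile_list(profiles)),
            class = "cost_context")
}

#' Drug-repair optimization context
#'
#' Precomputes everything the dose optimizers need: the paced steady-state
#' wild-type biomarkers (the repair target), the paced steady state of the
#' untreated mutant (drug evaluations start from it, as a drug applied to
#' the established mutant phenotype), and a memoised objective that
#' simulates the mutant under the multiplicative drug factors and returns
#' the weighted biomarker cost.
#'
#' @param model A mutant `ap_model` (its `"WT"` counterpart defines the
#'   repair target).
#' @param profiles Drug profiles ([drug_profile()] list or `drug_library`).
#' @param protocol [pacing_protocol()] used for the baseline steady states.
#' @param spec A [cost_spec()].
#' @param eval_prebeats Conditioning beats per drug evaluation (started
#'   from the untreated mutant steady state).
#' @param ca_duration Calcium-duration convention, see [compute_biomarkers()].
#' @return An object of class `c("repair_context", "cost_context")` with
#'   elements `objective`, `wt_biomarkers`, `mutant_biomarkers`,
#'   `untreated_cost`, `profiles` and evaluation counters.
#' @export
repair_context <- function(model, profiles, protocol = pacing_protocol(),
                           spec = cost_spec(), eval_prebeats = 8,
                           ca_duration = "decay") {
  stopifnot(inherits(model, "ap_model"))
  profiles <- as_profile_list(profiles)
  wt_model <- set_mutation(model, "WT")
  mut_model <- model

  wt_tr <- simulate_ap(wt_model, protocol = protocol)
  wt_bio <- compute_biomarkers(wt_tr, ca_duration = ca_duration)
  mut_tr <- simulate_ap(mut_model, protocol = protocol)
  mut_bio <- compute_biomarkers(mut_tr, ca_duration = ca_duration)
  mut_init <- attr(mut_tr, "final_state")

  eval_protocol <- protocol
  eval_protocol$n_prebeats <- as.integer(eval_prebeats)

  cache <- new.env(parent = emptyenv())
  n_eval <- new.env(parent = emptyenv())
  n_eval$total <- 0L; n_eval$simulated <- 0L
  untreated_cost <- biomarker_distance(mut_bio, wt_bio, spec)
  # the zero-dose evaluation is the untreated baseline itself
  cache[["untreated"]] <- list(cost = untreated_cost, biomarkers = mut_bio,
                               censored = length(attr(mut_bio, "censored")) > 0)

  evaluate <- function(doses) {
    doses <- doses[doses > 0]
    key <- if (length(doses))
      paste(names(doses), signif(doses, 6), sep = "=", collapse = ";")
    else "untreated"
    if (!is.null(cache[[key]])) return(cache[[key]])
    factors <- suppressWarnings(model_factors(mut_model, profiles, doses))
    tr <- simulate_ap(mut_model, factors = factors, protocol = eval_protocol,
                      init = mut_init)
    bio <- compute_biomarkers(tr, ca_duration = ca_duration)
    cost <- biomarker_distance(bio, wt_bio, spec)
    res <- list(cost = cost, biomarkers = bio,
                censored = length(attr(bio, "censored")) > 0)
    cache[[key]] <- res
    n_eval$simulated <- n_eval$simulated + 1L
    res
  }

  objective <- function(doses) {
    n_eval$total <- n_eval$total + 1L
    evaluate(doses)$cost
  }

  structure(list(objective = objective,
                 evaluate = evaluate,
                 profiles = profiles,
                 wt_biomarkers = wt_bio,
                 mutant_biomarkers = mut_bio,
                 untreated_cost = untreated_cost,
                 spec = spec,
                 protocol = protocol,
                 mutant_init = mut_init,
                 model = mut_model,
                 counters = n_eval),
            class = c("repair_context", "cost_context"))
}

#' Weighted biomarker cost of a dose vector
#'
#' Simulates the context's mutant model under the multiplicative combination
#' factors of `doses`, extracts biomarkers and returns the weighted relative
#' deviation from the wild-type panel. The zero-dose cost equals the
#' untreated mutant cost; a censored biomarker (threshold not re-crossed
#' within the beat) enters at its beat-end value and sets the `censored`
#' attribute.
#'
#' @param context A [repair_context()].
#' @param doses Named dose vector (uM); an empty vector gives the untreated
#'   cost.
#' @return Nonnegative scalar with attributes `biomarkers` and `censored`.
#' @export
ap_cost <- function(context, doses = numeric(0)) {
  stopifnot(inherits(context, "repair_context"))
  dose_vector(doses, context$profiles)
  res <- context$evaluate(doses)
  structure(res$cost, biomarkers = res$biomarkers, censored = res$censored)
}
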