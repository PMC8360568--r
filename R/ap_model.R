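# Fixed current and state orderings shared with the compiled RHS.
.AP_CURRENTS <- c("I_Na", "I_NaL", "I_CaL", "I_Kr", "I_Ks", "I_K1",
                  "I_to", "I_f", "I_NaCa", "I_NaK", "I_bCl", "I_bCa")
.AP_STATES <- c("v", "m", "h", "j", "hL", "d", "f", "xr1", "xs", "s",
                "y", "cai", "casr")
.CELL_TYPES <- c("adult-human", "rabbit", "hiPSC-CM")

#' Build an action-potential model from a parameter file
#'
#' Loads a model parameter file (YAML, schema `aprepair-ap-model-1`) and
#' instantiates it for one cell type and mutation status. Every membrane
#' current is stored as `I_i = rho_i * J_i`: the channel-density scaling
#' `rho_i` is the only quantity that differs between cell types (maturation
#' or species translation), while the flux `J_i` (conductance `g0`, gating,
#' reversal potential) is the only part touched by the mutation and by
#' drugs. The SQT1 N588K mutation replaces the wild-type I_Kr inactivation
#' steady state by its shifted variant (see [xkr2_inf()]); nothing else
#' changes.
#'
#' The package ships a synthetic surrogate parameter set
#' (`extdata/surrogate_model.yaml`); externally published parameter sets
#' following the same schema can be dropped in.
#'
#' @param path Path to the model YAML file; defaults to the shipped
#'   surrogate set.
#' @param cell_type `"adult-human"`, `"rabbit"` or `"hiPSC-CM"`.
#' @param mutation `"WT"` or `"N588K"`.
#' @return An object of class `ap_model`.
#' @export
build_ap_model <- function(path = NULL,
                           cell_type = c("adult-human", "rabbit", "hiPSC-CM"),
                           mutation = c("WT", "N588K")) {
  cell_type <- match.arg(cell_type)
  mutation <- match.arg(mutation)
  if (is.null(path))
    path <- system.file("extdata", "surrogate_model.yaml",
                        package = "aprepair", mustWork = TRUE)
  if (!file.exists(path)) stop("model file not found: ", path, call. = FALSE)
  raw <- yaml::read_yaml(path)
  if (!identical(raw$schema, "aprepair-ap-model-1"))
    stop("model file '", path, "': unknown or missing schema", call. = FALSE)

  cur_ids <- names(raw$currents)
  unknown <- setdiff(cur_ids, .AP_CURRENTS)
  if (length(unknown))
    stop("unknown current_id in model file: ", paste(unknown, collapse = ", "),
         call. = FALSE)
  missing <- setdiff(.AP_CURRENTS, cur_ids)
  if (length(missing))
    stop("model file lacks required current(s): ", paste(missing, collapse = ", "),
         call. = FALSE)

  g0 <- vapply(.AP_CURRENTS, function(id) {
    g <- raw$currents[[id]]$g0
    if (is.null(g) || !is.numeric(g) || g < 0)
      stop("current '", id, "': missing or invalid g0", call. = FALSE)
    as.numeric(g)
  }, numeric(1))

  rho_profiles <- sapply(.AP_CURRENTS, function(id) {
    rho <- raw$currents[[id]]$rho
    vapply(.CELL_TYPES, function(ct) {
      r <- rho[[ct]]
      if (is.null(r))
        stop("current '", id, "': no rho for cell type '", ct, "'", call. = FALSE)
      if (!is.numeric(r) || r < 0)
        stop("current '", id, "': rho for '", ct, "' must be >= 0", call. = FALSE)
      as.numeric(r)
    }, numeric(1))
  })  # matrix cell_type x current

  init <- unlist(raw$initial_state)
  if (!all(.AP_STATES %in% names(init)))
    stop("initial_state must provide: ", paste(.AP_STATES, collapse = ", "),
         call. = FALSE)
  init <- init[.AP_STATES]

  need_const <- c("E_Na", "E_K", "E_CaL", "E_f", "E_Cl", "naca_a", "ksat",
                  "kCa", "cao", "fca_k")
  need_ca <- c("Vmaxup", "Kup", "krel", "kleak", "vc_vsr")
  consts <- unlist(raw$constants)
  cap <- unlist(raw$calcium)
  if (!all(need_const %in% names(consts)))
    stop("model file 'constants' must provide: ", paste(need_const, collapse = ", "),
         call. = FALSE)
  if (!all(need_ca %in% names(cap)))
    stop("model file 'calcium' must provide: ", paste(need_ca, collapse = ", "),
         call. = FALSE)

  structure(list(
    name = raw$name %||% basename(path),
    g0 = g0,
    rho_profiles = rho_profiles,
    constants = consts[need_const],
    calcium = cap[need_ca],
    initial_state = init,
    cell_type = cell_type,
    mutation = mutation,
    source = path
  ), class = "ap_model")
}

#' @export
print.ap_model <- function(x, ...) {
  cat(sprintf("<ap_model> %s | cell type: %s | mutation: %s\n",
              x$name, x$cell_type, x$mutation))
  cat("  currents:", paste(.AP_CURRENTS, collapse = ", "), "\n")
  invisible(x)
}

#' Channel-density scalings of a model
#'
#' @param model An [build_ap_model()] object.
#' @return Named vector of rho values for the model's cell type.
#' @export
model_rho <- function(model) {
  stopifnot(inherits(model, "ap_model"))
  rho <- model$rho_profiles[model$cell_type, ]
  names(rho) <- .AP_CURRENTS
  rho
}

#' Translate a model to another cell type
#'
#' Re-instantiates the model for a different cell type. Only the channel
#' density scalings `rho_i` change; the flux parameters, gate kinetics and
#' the mutation status are carried over untouched, so the drug factors
#' applicable to the source cell type are identical for the target.
#'
#' @param model An `ap_model`.
#' @param cell_type Target cell type.
#' @return The translated `ap_model`.
#' @export
translate_cell_type <- function(model,
                                cell_type = c("adult-human", "rabbit", "hiPSC-CM")) {
  stopifnot(inherits(model, "ap_model"))
  cell_type <- match.arg(cell_type)
  model$cell_type <- cell_type
  model
}

#' Switch the mutation status of a model
#'
#' Only the I_Kr inactivation-gate variant changes (see [xkr2_inf()]); all
#' channel densities are left untouched.
#'
#' @param model An `ap_model`.
#' @param mutation `"WT"` or `"N588K"`.
#' @return The modified `ap_model`.
#' @export
set_mutation <- function(model, mutation = c("WT", "N588K")) {
  stopifnot(inherits(model, "ap_model"))
  model$mutation <- match.arg(mutation)
  model
}

#' Per-current drug combination factors for a model
#'
#' Evaluates the multiplicative combination factor of every model current
#' at the given doses. Drug effects on currents the model does not carry
#' are ignored with a warning, so one drug library can serve reduced
#' models. The factors depend only on the drug profiles and doses -- never
#' on the cell type, channel densities or mutation status of the model.
#'
#' @param model An `ap_model`.
#' @param profiles Drug profiles.
#' @param doses Named dose vector (uM).
#' @return Named vector of per-current scale factors (all 1 when no doses).
#' @export
model_factors <- function(model, profiles = NULL, doses = NULL) {
  factors <- rep(1, length(.AP_CURRENTS))
  names(factors) <- .AP_CURRENTS
  if (is.null(profiles) || is.null(doses) || length(doses) == 0L)
    return(factors)
  profiles <- as_profile_list(profiles)
  dose_vector(doses, profiles)
  touched <- unique(unlist(lapply(profiles[names(doses)],
                                  function(p) names(p$effects))))
  extra <- setdiff(touched, .AP_CURRENTS)
  if (length(extra))
    warning("drug effect(s) on current(s) absent from the model ignored: ",
            paste(extra, collapse = ", "), call. = FALSE)
  for (cur in intersect(touched, .AP_CURRENTS))
    factors[[cur]] <- combined_factor(profiles, doses, cur)
  factors
}

# Flat parameter vector for the compiled RHS. 'factors' are per-current
# multiplicative drug factors (missing entries default to 1).
model_parms <- function(model, factors = NULL, protocol = pacing_protocol(),
                        stimulate = TRUE) {
  stopifnot(inherits(model, "ap_model"))
  f <- rep(1, length(.AP_CURRENTS))
  names(f) <- .AP_CURRENTS
  if (!is.null(factors)) {
    if (is.null(names(factors))) stop("'factors' must be named by current_id",
                                      call. = FALSE)
    bad <- setdiff(names(factors), .AP_CURRENTS)
    if (length(bad)) stop("unknown current_id in factors: ",
                          paste(bad, collapse = ", "), call. = FALSE)
    if (any(!is.finite(factors)) || any(factors < 0))
      stop("drug factors must be finite and >= 0", call. = FALSE)
    f[names(factors)] <- factors
  }
  geff <- model$g0 * model_rho(model) * f
  mut <- model$mutation == "N588K"
  co <- model$constants
  ca <- model$calcium
  c(stim_amp = if (stimulate) protocol$stimulus_amplitude else 0,
    stim_start = 0,
    stim_dur = protocol$stimulus_duration,
    xkr2_vshift = if (mut) 62 else 0,
    xkr2_slope = if (mut) 20.9 * 1.85 else 20.9,
    geff,
    co[c("E_Na", "E_K", "E_CaL", "E_f", "E_Cl", "naca_a", "ksat", "kCa")],
    ca[c("Vmaxup", "Kup", "krel", "kleak", "vc_vsr")],
    Bufc = 0.15, Kbufc = 0.001, Bufsr = 10, Kbufsr = 0.3,
    fca_k = unname(co[["fca_k"]]), cao = unname(co[["cao"]]))
}

#' Evaluate instantaneous membrane currents at a state
#'
#' Pure-R mirror of the compiled right-hand side's current formulas; used
#' for inspection and for verifying the density/flux orthogonality of the
#' model (mutation and drug effects act on the flux, cell type only on the
#' density).
#'
#' @param model An `ap_model`.
#' @param state Named state vector (`v`, gates, `cai`, `casr`); defaults to
#'   the model's initial state.
#' @param factors Optional named per-current drug factors.
#' @return Named vector of the 12 membrane currents in A/F.
#' @export
eval_currents <- function(model, state = model$initial_state, factors = NULL) {
  stopifnot(inherits(model, "ap_model"))
  state <- state[.AP_STATES]
  if (any(is.na(state))) stop("'state' must name all state variables", call. = FALSE)
  p <- model_parms(model, factors)
  sig <- function(x) 1 / (1 + exp(x))
  VT <- 26.7
  v <- state[["v"]]; cai <- max(state[["cai"]], 1e-7)
  mL_inf <- sig(-(v + 42) / 5)
  xkr2 <- sig((v + 70 - p[["xkr2_vshift"]]) / p[["xkr2_slope"]])
  r_inf <- sig(-(v - 5) / 9)
  k1_inf <- sig((v - p[["E_K"]] - 10) / 12)
  fca <- 1 / (1 + (cai / p[["fca_k"]])^2)
  E_Ca <- 0.5 * VT * log(p[["cao"]] / cai)
  e1 <- exp(0.35 * v / VT); e2 <- exp(-0.65 * v / VT)
  c(I_Na  = p[["I_Na"]] * state[["m"]]^3 * state[["h"]] * state[["j"]] *
            (v - p[["E_Na"]]),
    I_NaL = p[["I_NaL"]] * mL_inf * state[["hL"]] * (v - p[["E_Na"]]),
    I_CaL = p[["I_CaL"]] * state[["d"]] * state[["f"]] * fca * (v - p[["E_CaL"]]),
    I_Kr  = p[["I_Kr"]] * state[["xr1"]] * xkr2 * (v - p[["E_K"]]),
    I_Ks  = p[["I_Ks"]] * state[["xs"]]^2 * (v - p[["E_K"]]),
    I_K1  = p[["I_K1"]] * k1_inf * (v - p[["E_K"]]),
    I_to  = p[["I_to"]] * r_inf * state[["s"]] * (v - p[["E_K"]]),
    I_f   = p[["I_f"]] * state[["y"]] * (v - p[["E_f"]]),
    I_NaCa = p[["I_NaCa"]] * (e1 * p[["naca_a"]] - e2 * cai) /
             (1 + p[["ksat"]] * e2),
    I_NaK = p[["I_NaK"]] / (1 + 0.1245 * exp(-0.1 * v / VT) +
                              0.0353 * exp(-v / VT)),
    I_bCl = p[["I_bCl"]] * (v - p[["E_Cl"]]),
    I_bCa = p[["I_bCa"]] * (v - E_Ca))
}
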