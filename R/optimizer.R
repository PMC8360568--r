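#' Upper dose bounds for the optimizer
#'
#' Computes one upper bound per drug according to a bounding mode:
#' \describe{
#'   \item{`saturation-cap`}{The dose at which the drug's most potent
#'     target current reaches 95% of its maximum effect:
#'     `min over entries of EC50 * (0.95/0.05)^(1/H)`. This is the default
#'     "maximal allowed dose" of unconstrained searches.}
#'   \item{`min-ec50`}{The smallest EC50 among the drug's target currents.}
#'   \item{`half-min-ec50`}{Half of `min-ec50`: the strict low-dose
#'     restriction `D <= min(EC50)/2`.}
#'   \item{`explicit`}{User-supplied bounds (named vector, uM).}
#' }
#'
#' @param profiles Drug profiles.
#' @param mode Bounding mode, see above.
#' @param bounds Named numeric vector of explicit bounds (uM), required for
#'   `mode = "explicit"`.
#' @param saturation Saturation fraction of `saturation-cap` (default 0.95).
#' @return Named vector of positive upper bounds (uM), class `dose_bounds`.
#' @export
dose_bounds <- function(profiles,
                        mode = c("saturation-cap", "min-ec50",
                                 "half-min-ec50", "explicit"),
                        bounds = NULL, saturation = 0.95) {
  mode <- match.arg(mode)
  profiles <- as_profile_list(profiles)
  out <- switch(mode,
    "explicit" = {
      if (is.null(bounds) || is.null(names(bounds)))
        stop("mode 'explicit' needs a named 'bounds' vector (uM)", call. = FALSE)
      if (!all(names(profiles) %in% names(bounds)))
        stop("explicit bounds missing for: ",
             paste(setdiff(names(profiles), names(bounds)), collapse = ", "),
             call. = FALSE)
      bounds[names(profiles)]
    },
    "min-ec50" = vapply(profiles, function(p)
      min(vapply(p$effects, function(e) 1 / e$eps, numeric(1))), numeric(1)),
    "half-min-ec50" = vapply(profiles, function(p)
      min(vapply(p$effects, function(e) 1 / e$eps, numeric(1))) / 2, numeric(1)),
    "saturation-cap" = {
      if (saturation <= 0 || saturation >= 1)
        stop("'saturation' must be in (0, 1)", call. = FALSE)
      vapply(profiles, function(p)
        min(vapply(p$effects, function(e)
          (saturation / (1 - saturation))^(1 / e$hill) / e$eps, numeric(1))),
        numeric(1))
    })
  if (any(out <= 0) || any(!is.finite(out)))
    stop("dose bounds must be positive and finite", call. = FALSE)
  structure(out, mode = mode, class = c("dose_bounds", "numeric"))
}

# Sum of dose / min-EC50 ratios: the low-dose preference used to break
# near-ties (cost within tie_tol) between candidate solutions.
.dose_load <- function(profiles, doses) {
  if (!length(doses) || is.null(profiles)) return(sum(doses))
  sum(vapply(names(doses), function(drug) {
    p <- profiles[[drug]]
    if (is.null(p)) return(doses[[drug]])
    doses[[drug]] / min(vapply(p$effects, function(e) 1 / e$eps, numeric(1)))
  }, numeric(1)))
}

# Bounded Nelder-Mead in unit coordinates u = dose/bound, clamping the
# objective inside the box and penalising excursions; deterministic.
.minimize_box <- function(fn, start_u, upper, reltol = 1e-4, maxit = NULL) {
  n <- length(start_u)
  if (is.null(maxit)) maxit <- 200L * n
  pen_fn <- function(u) {
    uc <- clamp(u, 0, 1)
    fn(uc * upper) + 1e3 * sum((u - uc)^2)
  }
  if (n == 1L) {
    # golden-section refinement around the start
    lo <- max(0, start_u - 0.5); hi <- min(1, start_u + 0.5)
    opt <- stats::optimize(function(u) fn(u * upper), lower = lo, upper = hi,
                           tol = 1e-4)
    cand_u <- c(opt$minimum, start_u)
    costs <- c(opt$objective, fn(start_u * upper))
    best <- which.min(costs)
    return(list(u = cand_u[best], cost = costs[best]))
  }
  res <- stats::optim(start_u, pen_fn, method = "Nelder-Mead",
                      control = list(reltol = reltol, maxit = maxit))
  u <- clamp(res$par, 0, 1)
  list(u = u, cost = fn(u * upper))
}

.result <- function(doses, cost, context, search = NULL) {
  structure(list(doses = doses, cost = cost, search = search),
            class = "optimization_result")
}

#' @export
print.optimization_result <- function(x, ...) {
  cat(sprintf("<optimization_result> cost = %.6g\n", x$cost))
  if (length(x$doses)) {
    for (d in names(x$doses))
      cat(sprintf("  %-14s %.6g uM\n", d, x$doses[[d]]))
  } else cat("  (no drugs)\n")
  invisible(x)
}

#' Optimal dose of a single drug
#'
#' Minimises the context's cost over the dose of one drug in `[0, bound]`.
#' The search is deterministic: a fixed 5-point lattice on the dose
#' interval is screened, the best lattice points are refined by bounded
#' golden-section search, and the overall best is returned (tie-broken
#' towards the lower dose).
#'
#' @param drug A [drug_profile()] (or drug name found in the context's
#'   profiles).
#' @param bound Positive upper dose bound (uM); see [dose_bounds()].
#' @param context A [repair_context()] or [objective_context()].
#' @param n_lattice Lattice size (default 5).
#' @return An `optimization_result` with elements `doses` (length-1 named
#'   vector) and `cost`.
#' @export
optimize_single <- function(drug, bound, context, n_lattice = 5) {
  if (is.character(drug)) {
    drug <- context$profiles[[drug]]
    if (is.null(drug)) stop("drug not found in context profiles", call. = FALSE)
  }
  stopifnot(inherits(drug, "drug_profile"))
  if (!is.numeric(bound) || length(bound) != 1 || !is.finite(bound) || bound <= 0)
    stop("'bound' must be a positive finite dose (uM)", call. = FALSE)
  fn <- function(d) context$objective(stats::setNames(d, drug$name))

  lattice <- seq(0, 1, length.out = n_lattice)
  lat_cost <- vapply(lattice, function(u) fn(u * bound), numeric(1))
  search <- data.frame(dose = lattice * bound, cost = lat_cost)

  # refine around the two best lattice points, then pick the overall best,
  # breaking near-ties (1e-4 in cost) towards the lower dose
  cand_u <- lattice
  cand_cost <- lat_cost
  for (i in order(lat_cost)[1:2]) {
    lo <- lattice[max(1L, i - 1L)]; hi <- lattice[min(n_lattice, i + 1L)]
    opt <- stats::optimize(function(u) fn(u * bound), lower = lo, upper = hi,
                           tol = 1e-4)
    cand_u <- c(cand_u, opt$minimum)
    cand_cost <- c(cand_cost, opt$objective)
  }
  ord <- order(cand_cost, cand_u)
  best <- ord[1]
  for (i in ord[-1])
    if (cand_cost[i] < cand_cost[best] + 1e-4 && cand_u[i] < cand_u[best])
      best <- i
  best_u <- cand_u[best]
  if (best_u * bound < 1e-9) best_u <- 0
  .result(stats::setNames(best_u * bound, drug$name), fn(best_u * bound),
          context, search)
}

#' Incremental optimization over growing drug combinations
#'
#' Builds optimal combinations of 1, 2, ..., `max_drugs` drugs by
#' continuation: the best n-drug solution seeds every candidate
#' (n+1)-drug search with the additional drug started at dose zero, so the
#' reported cost sequence is non-increasing in n. For n = 1 and each
#' two-drug candidate, a fixed 5-point-per-dimension lattice is screened
#' and the best points refined (deterministic multistart); for n > 2 only
#' the continuation start is refined.
#'
#' @param profiles Drug profiles to combine (`drug_library` or list of
#'   [drug_profile()]).
#' @param bounds A [dose_bounds()] vector covering all profiles.
#' @param context A [repair_context()] or [objective_context()].
#' @param max_drugs Largest combination size (<= number of drugs).
#' @param n_refine How many screened lattice starts are refined locally.
#' @param tie_tol Cost tolerance under which the lower-dose candidate wins.
#' @return List of `optimization_result`, element `n` for the best n-drug
#'   combination; drugs with optimal dose 0 are kept in the dose vector.
#' @export
optimize_incremental <- function(profiles, bounds, context, max_drugs = NULL,
                                 n_refine = 3, tie_tol = 1e-4) {
  profiles <- as_profile_list(profiles)
  K <- length(profiles)
  if (is.null(max_drugs)) max_drugs <- K
  stopifnot(K >= 1, max_drugs >= 1, max_drugs <= K)
  if (!all(names(profiles) %in% names(bounds)))
    stop("bounds missing for: ",
         paste(setdiff(names(profiles), names(bounds)), collapse = ", "),
         call. = FALSE)

  results <- vector("list", max_drugs)

  # n = 1: best single drug; the per-drug optima are kept in the result's
  # search trace (the diagonal of a pairwise cost matrix)
  singles <- lapply(names(profiles), function(drug)
    optimize_single(profiles[[drug]], bounds[[drug]], context))
  names(singles) <- names(profiles)
  results[[1]] <- .pick_best(singles, context$profiles, tie_tol)
  results[[1]]$search <- data.frame(
    candidate = names(singles),
    dose = vapply(singles, function(r) unname(r$doses), numeric(1)),
    cost = vapply(singles, `[[`, numeric(1), "cost"))

  if (max_drugs >= 2) {
    for (n in 2:max_drugs) {
      base <- results[[n - 1]]$doses
      remaining <- setdiff(names(profiles), names(base))
      candidates <- lapply(remaining, function(drug) {
        sel <- c(names(base), drug)
        upper <- unlist(bounds[sel])
        fn <- function(d) context$objective(stats::setNames(d, sel))
        start_u <- c(unname(base) / unlist(bounds[names(base)]), 0)
        starts <- list(start_u)
        if (n == 2) {
          lat <- as.matrix(expand.grid(seq(0, 1, length.out = 5),
                                       seq(0, 1, length.out = 5)))
          lat_cost <- apply(lat, 1, function(u) fn(u * upper))
          keep <- order(lat_cost)[seq_len(min(n_refine, nrow(lat)))]
          starts <- c(starts, lapply(keep, function(i) unname(lat[i, ])))
        }
        best <- NULL
        for (s in starts) {
          r <- .minimize_box(fn, s, upper)
          if (is.null(best) || r$cost < best$cost - tie_tol ||
              (r$cost < best$cost + tie_tol &&
               .dose_load(context$profiles, stats::setNames(r$u * upper, sel)) <
               .dose_load(context$profiles, stats::setNames(best$u * upper, sel))))
            best <- r
        }
        doses <- stats::setNames(best$u * upper, sel)
        doses[doses < 1e-9] <- 0
        cost <- fn(doses)
        # low-dose preference: a drug whose removal costs at most tie_tol
        # (and keeps the continuation guarantee) is dropped to zero
        for (k in order(doses, decreasing = FALSE)) {
          if (doses[k] == 0) next
          trial <- doses; trial[k] <- 0
          ct <- fn(trial)
          if (ct <= cost + tie_tol && ct <= results[[n - 1]]$cost) {
            doses <- trial; cost <- ct
          }
        }
        .result(doses, cost, context)
      })
      names(candidates) <- remaining
      best_n <- .pick_best(candidates, context$profiles, tie_tol)
      best_n$search <- data.frame(
        candidate = remaining,
        cost = vapply(candidates, `[[`, numeric(1), "cost"))
      # continuation guarantee: appending the new drug at dose 0 can never
      # be worse than the n-1 solution
      if (best_n$cost > results[[n - 1]]$cost) {
        doses <- c(base, stats::setNames(0, names(candidates)[1]))
        best_n <- .result(doses, results[[n - 1]]$cost, context)
      }
      results[[n]] <- best_n
    }
  }
  results
}

.pick_best <- function(candidates, profiles, tie_tol = 1e-4) {
  costs <- vapply(candidates, `[[`, numeric(1), "cost")
  loads <- vapply(candidates, function(r) .dose_load(profiles, r$doses),
                  numeric(1))
  ord <- order(costs, loads)
  best <- ord[1]
  for (i in ord[-1])
    if (costs[i] < costs[best] + tie_tol && loads[i] < loads[best]) best <- i
  candidates[[best]]
}

#' Exhaustive two-drug scan
#'
#' Runs the bounded two-parameter minimisation for every unordered pair of
#' drugs and the single-drug optimisation on the diagonal, mirroring the
#' cost-matrix presentation of pairwise combination searches.
#'
#' @inheritParams optimize_incremental
#' @return A list with `cost_matrix` (symmetric K x K, single-drug optima
#'   on the diagonal), `dose_matrix` (named list of optimal dose vectors,
#'   keyed `"drugA|drugB"`), and `best` (the argmin
#'   `optimization_result`).
#' @export
pairwise_scan <- function(profiles, bounds, context, n_refine = 3,
                          tie_tol = 1e-4) {
  profiles <- as_profile_list(profiles)
  K <- length(profiles)
  stopifnot(K >= 2)
  nm <- names(profiles)
  M <- matrix(NA_real_, K, K, dimnames = list(nm, nm))
  doses <- list()
  best <- NULL
  for (i in seq_len(K)) {
    ri <- optimize_single(profiles[[i]], bounds[[nm[i]]], context)
    M[i, i] <- ri$cost
    doses[[paste(nm[i], nm[i], sep = "|")]] <- ri$doses
  }
  lat5 <- as.matrix(expand.grid(seq(0, 1, length.out = 5),
                                seq(0, 1, length.out = 5)))
  for (i in seq_len(K - 1)) for (j in (i + 1):K) {
    sel <- c(nm[i], nm[j])
    upper <- unlist(bounds[sel])
    fn <- function(d) context$objective(stats::setNames(d, sel))
    lat_cost <- apply(lat5, 1, function(u) fn(u * upper))
    keep <- order(lat_cost)[seq_len(min(n_refine, nrow(lat5)))]
    bestp <- NULL
    for (k in keep) {
      r <- .minimize_box(fn, unname(lat5[k, ]), upper)
      if (is.null(bestp) || r$cost < bestp$cost) bestp <- r
    }
    M[i, j] <- M[j, i] <- bestp$cost
    dv <- stats::setNames(bestp$u * upper, sel)
    dv[dv < 1e-9] <- 0
    doses[[paste(nm[i], nm[j], sep = "|")]] <- dv
    if (is.null(best) || bestp$cost < best$cost)
      best <- .result(dv, bestp$cost, context)
  }
  list(cost_matrix = M, dose_matrix = doses, best = best)
}
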