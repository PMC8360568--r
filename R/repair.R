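#' Run configuration for the end-to-end repair pipeline
#'
#' @param model_file Model parameter file; `NULL` for the shipped surrogate.
#' @param cell_type Cell type to instantiate.
#' @param mutation Mutant genotype to repair (the wild type of the same
#'   model is the target).
#' @param drug_library_file Drug library YAML; `NULL` for the shipped
#'   default.
#' @param drugs Drug names to consider; `NULL` selects the whole library,
#'   `character(0)` runs only the WT/mutant comparison.
#' @param bounds_mode Dose bound mode, see [dose_bounds()].
#' @param max_drugs Largest combination size for the incremental search;
#'   0 disables the search.
#' @param scan_pairs If `TRUE`, also compute the full two-drug cost matrix.
#' @param protocol A [pacing_protocol()].
#' @param eval_prebeats Conditioning beats per optimizer evaluation.
#' @param out_dir Output directory (created if needed).
#' @param verbose Print stage progress.
#' @return A validated `run_config` list.
#' @export
run_config <- function(model_file = NULL, cell_type = "adult-human",
                       mutation = "N588K", drug_library_file = NULL,
                       drugs = NULL, bounds_mode = "saturation-cap",
                       max_drugs = 2, scan_pairs = FALSE,
                       protocol = pacing_protocol(), eval_prebeats = 8,
                       out_dir = "aprepair-results", verbose = TRUE) {
  if (!is.null(model_file) && !file.exists(model_file))
    stop("model file not found: ", model_file, call. = FALSE)
  if (!is.null(drug_library_file) && !file.exists(drug_library_file))
    stop("drug library file not found: ", drug_library_file, call. = FALSE)
  structure(list(model_file = model_file, cell_type = cell_type,
                 mutation = mutation, drug_library_file = drug_library_file,
                 drugs = drugs, bounds_mode = bounds_mode,
                 max_drugs = as.integer(max_drugs),
                 scan_pairs = isTRUE(scan_pairs), protocol = protocol,
                 eval_prebeats = eval_prebeats,
                 out_dir = out_dir, verbose = isTRUE(verbose)),
            class = "run_config")
}

.say <- function(config, ...) if (config$verbose) message(sprintf(...))

# Biomarker comparison table: WT, untreated mutant, treated mutant and
# percent deviations from WT.
.comparison_table <- function(wt, mutant, treated = NULL) {
  pct <- function(x) 100 * (x - wt) / abs(wt)
  df <- data.frame(biomarker = names(wt),
                   WT = as.numeric(wt),
                   mutant = as.numeric(mutant),
                   mutant_pct_from_WT = as.numeric(pct(mutant)))
  if (!is.null(treated)) {
    df$treated <- as.numeric(treated)
    df$treated_pct_from_WT <- as.numeric(pct(treated))
  }
  df
}

# Dose report in the style of published optimal-dose tables: dose, the
# saturation fraction of the most affected current, and the percent change
# of every model current.
.dose_report <- function(profiles, doses, currents) {
  rows <- lapply(names(doses), function(drug) {
    p <- profiles[[drug]]
    sat <- max(vapply(p$effects, saturation_fraction, numeric(1),
                      dose = doses[[drug]]))
    data.frame(drug = drug, dose_uM = doses[[drug]],
               max_pct_of_E = 100 * sat)
  })
  rep_df <- do.call(rbind, rows)
  pc <- percent_change_table(profiles, doses, currents)
  list(doses = rep_df, percent_change = as.data.frame(pc))
}

#' Run the full repair pipeline
#'
#' Simulates the wild-type and untreated mutant baselines, then (per
#' config) runs the pairwise two-drug scan and/or the incremental
#' combination search, writing traces, biomarker tables, dose reports and
#' a machine-readable JSON summary to the output directory.
#'
#' @param config A [run_config()].
#' @return Invisibly, a list with the context, optimization results and the
#'   summary; files are written to `config$out_dir`.
#' @export
run_repair <- function(config) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)

  .say(config, "building %s %s model", config$cell_type, config$mutation)
  model <- build_ap_model(config$model_file, cell_type = config$cell_type,
                          mutation = config$mutation)
  library <- if (is.null(config$drug_library_file)) default_drug_library()
             else load_drug_library(config$drug_library_file)
  drugs <- if (is.null(config$drugs)) names(library) else config$drugs
  unknown <- setdiff(drugs, names(library))
  if (length(unknown))
    stop("selected drug(s) not in library: ", paste(unknown, collapse = ", "),
         call. = FALSE)
  profiles <- library[drugs]
  class(profiles) <- "list"

  .say(config, "pacing wild-type and mutant baselines")
  wt_model <- set_mutation(model, "WT")
  wt_tr <- simulate_ap(wt_model, protocol = config$protocol,
                       include_currents = TRUE)
  mut_tr <- simulate_ap(model, protocol = config$protocol,
                        include_currents = TRUE)
  write_trace(wt_tr, file.path(config$out_dir, "trace_wt.tsv"))
  write_trace(mut_tr, file.path(config$out_dir, "trace_mutant.tsv"))
  wt_bio <- compute_biomarkers(wt_tr)
  mut_bio <- compute_biomarkers(mut_tr)
  write_biomarkers(wt_bio, file.path(config$out_dir, "biomarkers_wt.tsv"))
  write_biomarkers(mut_bio, file.path(config$out_dir, "biomarkers_mutant.tsv"))
  utils::write.table(.comparison_table(wt_bio, mut_bio),
                     file.path(config$out_dir, "biomarkers_untreated.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)

  summary <- list(
    model = model$name, cell_type = config$cell_type,
    mutation = config$mutation, drugs = drugs,
    bounds_mode = config$bounds_mode,
    untreated = list(APD90_wt = unname(wt_bio[["APD90"]]),
                     APD90_mutant = unname(mut_bio[["APD90"]]),
                     CaA_wt = unname(wt_bio[["CaA"]]),
                     CaA_mutant = unname(mut_bio[["CaA"]])))
  results <- list(wt_biomarkers = wt_bio, mutant_biomarkers = mut_bio)

  if (length(drugs)) {
    ctx <- repair_context(model, profiles, protocol = config$protocol,
                          eval_prebeats = config$eval_prebeats)
    bounds <- dose_bounds(profiles, mode = config$bounds_mode)
    summary$untreated_cost <- ctx$untreated_cost
    results$context <- ctx

    if (config$scan_pairs && length(drugs) >= 2) {
      .say(config, "pairwise two-drug scan over %d drugs", length(drugs))
      scan <- pairwise_scan(profiles, bounds, ctx)
      utils::write.table(
        cbind(data.frame(drug = rownames(scan$cost_matrix)),
              as.data.frame(scan$cost_matrix)),
        file.path(config$out_dir, "pair_costs.tsv"),
        sep = "\t", quote = FALSE, row.names = FALSE)
      results$pairwise <- scan
      summary$best_pair <- list(doses = as.list(scan$best$doses),
                                cost = scan$best$cost)
    }

    if (config$max_drugs >= 1) {
      .say(config, "incremental search up to %d drugs", config$max_drugs)
      inc <- optimize_incremental(profiles, bounds, ctx,
                                  max_drugs = min(config$max_drugs,
                                                  length(drugs)))
      results$incremental <- inc
      summary$incremental <- lapply(inc, function(r)
        list(doses = as.list(r$doses), cost = r$cost))
      for (n in seq_along(inc)) {
        r <- inc[[n]]
        treated <- attr(ap_cost(ctx, r$doses), "biomarkers")
        utils::write.table(
          .comparison_table(ctx$wt_biomarkers, ctx$mutant_biomarkers, treated),
          file.path(config$out_dir, sprintf("biomarkers_best_%d_drugs.tsv", n)),
          sep = "\t", quote = FALSE, row.names = FALSE)
        rel <- .dose_report(ctx$profiles, r$doses[r$doses > 0], .AP_CURRENTS)
        if (!is.null(rel$doses))
          utils::write.table(
            rel$doses,
            file.path(config$out_dir, sprintf("doses_best_%d_drugs.tsv", n)),
            sep = "\t", quote = FALSE, row.names = FALSE)
        utils::write.table(
          rel$percent_change,
          file.path(config$out_dir, sprintf("percent_change_best_%d_drugs.tsv", n)),
          sep = "\t", quote = FALSE, row.names = FALSE)
      }
      summary$evaluations <- ctx$counters$simulated
    }
  }

  jsonlite::write_json(summary, file.path(config$out_dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  .say(config, "done: %s", config$out_dir)
  invisible(c(results, list(summary = summary)))
}
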