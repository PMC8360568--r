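#' Load a drug library from a YAML file
#'
#' A drug library file has a top-level `drugs` mapping with one block per
#' drug and one sub-block per affected ion current, carrying the keys
#' `ec50_uM`, `hill`, `emax` and optionally `source`. The library shipped
#' with the package (`default_drug_library()`) contains nine drugs
#' characterised against the SQT1 (hERG N588K) mutant `I_Kr` and wild-type
#' `I_CaL`, `I_Na`, `I_NaL` and `I_f` currents. Currents without an entry are
#' treated as unaffected by the drug.
#'
#' @param path Path to a YAML drug library.
#' @return Named list of [drug_profile()] objects, class `drug_library`.
#' @seealso [write_drug_library()] for the lossless inverse.
#' @export
load_drug_library <- function(path) {
  if (!file.exists(path)) stop("drug library file not found: ", path, call. = FALSE)
  raw <- yaml::read_yaml(path)
  if (is.null(raw$drugs) || !is.list(raw$drugs) || !length(raw$drugs))
    stop("drug library '", path, "': missing or empty 'drugs' mapping", call. = FALSE)
  profiles <- lapply(names(raw$drugs), function(drug) {
    block <- raw$drugs[[drug]]
    if (!is.list(block) || !length(block))
      stop("drug '", drug, "': expected at least one current block", call. = FALSE)
    effects <- lapply(names(block), function(cur) {
      entry <- block[[cur]]
      for (key in c("ec50_uM", "hill", "emax"))
        if (is.null(entry[[key]]) || !is.numeric(entry[[key]]))
          stop("drug '", drug, "', current '", cur, "': missing or non-numeric '",
               key, "'", call. = FALSE)
      tryCatch(
        hill_effect(entry$ec50_uM, entry$hill, entry$emax, source = entry$source),
        error = function(e) stop("drug '", drug, "', current '", cur, "': ",
                                 conditionMessage(e), call. = FALSE))
    })
    names(effects) <- names(block)
    drug_profile(drug, effects)
  })
  names(profiles) <- names(raw$drugs)
  structure(profiles, class = c("drug_library", "list"))
}

#' The drug library shipped with the package
#'
#' @return A `drug_library` (named list of [drug_profile()]).
#' @export
default_drug_library <- function() {
  load_drug_library(system.file("extdata", "drug_library.yaml",
                                package = "aprepair", mustWork = TRUE))
}

#' Serialize a drug library back to YAML
#'
#' Field-by-field inverse of [load_drug_library()]: loading the written file
#' reproduces every EC50, Hill coefficient, maximum effect and source note.
#'
#' @param library A `drug_library` or named list of [drug_profile()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_drug_library <- function(library, path) {
  profiles <- as_profile_list(library)
  drugs <- lapply(profiles, function(p) {
    lapply(p$effects, function(e) {
      out <- list(ec50_uM = 1 / e$eps, hill = e$hill, emax = e$emax)
      if (!is.na(e$source)) out$source <- e$source
      out
    })
  })
  yaml::write_yaml(list(schema = "aprepair-drug-library-1", drugs = drugs), path)
  invisible(path)
}

#' @export
print.drug_library <- function(x, ...) {
  cat(sprintf("<drug_library> %d drugs: %s\n", length(x),
              paste(names(x), collapse = ", ")))
  invisible(x)
}
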