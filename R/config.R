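#' Run configuration
#'
#' Collects every tunable constant of the pipeline: compartment volumes used
#' to convert molar amounts to concentrations, identification-quality filter
#' thresholds, cargo category thresholds, and the baseline-imputation window.
#'
#' Defaults reproduce the oocyte study conditions: a 50 nl nucleus and a
#' 500 nl yolk-free cytosol, peptides with posterior error probability (PEP)
#' above 0.01 excluded, a minimum of two unique peptides for cargo
#' quantification, and a detectability baseline taken as the median intensity
#' of the 30 least abundant proteins of a sample.
#'
#' @param volumes named list with elements `nucleus` and `cytosol`,
#'   compartment volumes in nanolitres. Must be positive.
#' @param max_pep maximum tolerated minimum-peptide PEP per protein.
#' @param min_unique_peptides minimum unique peptides required to quantify a
#'   protein in cargo mode.
#' @param site_rule policy for the "only identified by site" flag in
#'   partition mode: `"single_compartment"` (default; drop flagged proteins
#'   detected in only one compartment) or `"always"` (drop all flagged).
#' @param species species profile for cargo category thresholds; passed to
#'   [category_thresholds()].
#' @param thresholds a list as returned by [category_thresholds()]; overrides
#'   `species` when supplied.
#' @param k_baseline window for baseline imputation: the baseline is the
#'   median intensity of the `k_baseline` least abundant detected proteins.
#' @param averaging how per-replicate concentrations are combined:
#'   `"arithmetic"` (default) or `"geometric"` mean on the linear scale.
#' @param pseudo_ratio if `TRUE`, proteins detected in a single compartment
#'   get a pseudo N:C ratio by substituting the smallest observed
#'   concentration of the missing compartment; default `FALSE` (censored
#'   proteins are reported by status only).
#' @param seed integer seed recorded with the configuration.
#'
#' @return a list of class `run_config`.
#' @export
run_config <- function(volumes = list(nucleus = 50, cytosol = 500),
                       max_pep = 0.01,
                       min_unique_peptides = 2L,
                       site_rule = c("single_compartment", "always"),
                       species = "xenopus",
                       thresholds = NULL,
                       k_baseline = 30L,
                       averaging = c("arithmetic", "geometric"),
                       pseudo_ratio = FALSE,
                       seed = 1L) {
  site_rule <- match.arg(site_rule)
  averaging <- match.arg(averaging)
  if (!is.list(volumes) || !all(c("nucleus", "cytosol") %in% names(volumes))) {
    abort_arg("`volumes` must be a list with elements `nucleus` and `cytosol`")
  }
  assert_scalar_number(volumes$nucleus, "volumes$nucleus", 0, strict = TRUE)
  assert_scalar_number(volumes$cytosol, "volumes$cytosol", 0, strict = TRUE)
  assert_scalar_number(max_pep, "max_pep", 0)
  assert_scalar_number(min_unique_peptides, "min_unique_peptides", 0)
  assert_scalar_number(k_baseline, "k_baseline", 1)
  thresholds <- thresholds %||% category_thresholds(species)
  structure(
    list(
      volumes = list(nucleus = as.numeric(volumes$nucleus),
                     cytosol = as.numeric(volumes$cytosol)),
      max_pep = max_pep,
      min_unique_peptides = as.integer(min_unique_peptides),
      site_rule = site_rule,
      species = species,
      thresholds = thresholds,
      k_baseline = as.integer(k_baseline),
      averaging = averaging,
      pseudo_ratio = isTRUE(pseudo_ratio),
      seed = as.integer(seed)
    ),
    class = "run_config"
  )
}

#' Cargo category thresholds
#'
#' Numeric gates for the cargo categories. The three printed frog thresholds
#' are fixed by the study (A1: RanGTP-stimulation >= 500-fold and enrichment
#' from input >= 3-fold; A2: enrichment >= 100-fold); the remaining gates are
#' package defaults, overridable per species.
#'
#' @param species species profile. `"xenopus"` is the reference profile;
#'   `"human"` and `"yeast"` currently default to the same gates.
#' @param ... named overrides, e.g. `a1 = list(min_stimulation = 200)`.
#'   Supplied elements are merged over the profile defaults.
#'
#' @return a list with elements `a1`, `a2`, `b`, `nonbinder`, `k_baseline`.
#' @export
category_thresholds <- function(species = c("xenopus", "human", "yeast"), ...) {
  species <- match.arg(species)
  base <- list(
    a1 = list(min_stimulation = 500, min_enrichment = 3,
              min_molar_fraction = 1e-4),
    a2 = list(min_enrichment = 100, min_stimulation_relaxed = 10),
    b = list(relax_factor = 1 / 3),
    nonbinder = list(max_enrichment = 0.2, min_input_molar_fraction = 1e-5),
    k_baseline = 30L
  )
  overrides <- list(...)
  for (nm in names(overrides)) {
    if (!nm %in% names(base)) abort_arg(sprintf("unknown threshold block `%s`", nm))
    base[[nm]] <- utils::modifyList(base[[nm]], as.list(overrides[[nm]]))
  }
  stopifnot(base$a1$min_enrichment <= base$a2$min_enrichment)
  base
}

#' Read / write a run configuration
#'
#' The configuration file is flat YAML; any subset of keys may be given and
#' the rest default as in [run_config()]. Unknown keys raise an error naming
#' the key.
#'
#' @param path file path.
#' @return `read_run_config()` returns a `run_config` list.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) abort_arg(sprintf("config file not found: %s", path))
  raw <- yaml::read_yaml(path)
  known <- names(formals(run_config))
  unknown <- setdiff(names(raw), known)
  if (length(unknown)) {
    abort_arg(sprintf("unknown config key(s): %s", paste(unknown, collapse = ", ")))
  }
  do.call(run_config, raw)
}

#' @rdname read_run_config
#' @param config a `run_config` list.
#' @export
write_run_config <- function(config, path) {
  stopifnot(inherits(config, "run_config"))
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' @export
print.run_config <- function(x, ...) {
  cat("<run_config>\n")
  cat(sprintf("  volumes: nucleus %g nl, cytosol %g nl\n",
              x$volumes$nucleus, x$volumes$cytosol))
  cat(sprintf("  filters: PEP <= %g, unique peptides >= %d, site rule '%s'\n",
              x$max_pep, x$min_unique_peptides, x$site_rule))
  cat(sprintf("  species profile: %s; baseline window k = %d\n",
              x$species, x$k_baseline))
  cat(sprintf("  replicate averaging: %s\n", x$averaging))
  invisible(x)
}
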