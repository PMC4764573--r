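# Quantitation: identification filters, proteoform merging, spike-in
# calibration, absolute concentrations, and N:C partition coefficients.

#' Apply identification-quality filters
#'
#' Removes unreliably identified proteins before quantitation. Two rule sets
#' exist:
#'
#' * `mode = "partition"` (fractionation data): proteins whose minimum
#'   peptide PEP exceeds `config$max_pep` (0.01 by default) are excluded, and
#'   proteins flagged "only identified by site" that were detected in only
#'   one compartment are excluded (a flag seen in both compartments is
#'   retained).
#' * `mode = "cargo"` (affinity data): proteins site-flagged within the
#'   RanGTP-containing bait sample are excluded, then the PEP rule, then a
#'   minimum of `config$min_unique_peptides` unique peptides (two, for the
#'   frog profile).
#'
#' Filters act at protein level: the protein's minimum PEP, its maximum
#' unique-peptide count and the disjunction of its site flags over records.
#'
#' @param table a long-form intensity table.
#' @param config a [run_config()].
#' @param mode `"partition"` or `"cargo"`.
#' @return a list with `table` (surviving records) and `log`, a tibble with
#'   one row per (protein, rule) removal.
#' @export
filter_records <- function(table, config = run_config(),
                           mode = c("partition", "cargo")) {
  mode <- match.arg(mode)
  validate_intensity_table(table)

  prot <- dplyr::summarise(
    dplyr::group_by(table, .data$protein_id),
    min_pep = min(.data$min_pep),
    unique_peptides = max(.data$unique_peptides),
    any_site = any(.data$only_by_site),
    .groups = "drop"
  )
  removed <- list()

  if (mode == "partition") {
    pep_fail <- prot$protein_id[prot$min_pep > config$max_pep]
    removed$pep <- pep_fail

    det <- dplyr::filter(table, !is.na(.data$intensity),
                         .data$role %in% c("nuclear", "cytosolic"))
    n_comp <- dplyr::summarise(dplyr::group_by(det, .data$protein_id),
                               n_comp = dplyr::n_distinct(.data$role),
                               .groups = "drop")
    site_ids <- prot$protein_id[prot$any_site]
    if (config$site_rule == "single_compartment") {
      one_comp <- n_comp$protein_id[n_comp$n_comp == 1L]
      # proteins never detected have no compartment evidence either
      undetected <- setdiff(prot$protein_id, n_comp$protein_id)
      removed$site <- intersect(site_ids, c(one_comp, undetected))
    } else {
      removed$site <- site_ids
    }
  } else {
    plus <- dplyr::filter(table, .data$role == "bait_plus_ran",
                          .data$only_by_site)
    removed$site_bait <- unique(plus$protein_id)
    removed$pep <- prot$protein_id[prot$min_pep > config$max_pep]
    removed$unique_peptides <-
      prot$protein_id[prot$unique_peptides < config$min_unique_peptides]
  }

  log <- dplyr::bind_rows(lapply(names(removed), function(rule) {
    if (!length(removed[[rule]])) return(NULL)
    tibble(protein_id = removed[[rule]], rule = rule, mode = mode)
  }))
  if (is.null(log) || nrow(log) == 0L) {
    log <- tibble(protein_id = character(), rule = character(),
                  mode = character())
  }
  drop <- unique(unlist(removed, use.names = FALSE))
  list(table = dplyr::filter(table, !.data$protein_id %in% drop), log = log)
}

#' Merge allelic proteoforms to unique proteins
#'
#' Collapses proteoform rows to their unique protein per sample: intensities
#' are summed (missing treated as zero; a value that is missing in every
#' member stays missing), unique-peptide counts are summed, the minimum PEP
#' is taken, and the site flag is the conjunction (a merged protein is
#' site-only if every member is).
#'
#' @param table a long-form intensity table keyed by proteoform ids.
#' @param map a data frame `proteoform_id` -> `unique_protein_id`. The map is
#'   made total: proteoforms absent from it map to themselves.
#' @return a long-form intensity table keyed by unique protein ids.
#' @export
merge_proteoforms <- function(table, map) {
  validate_intensity_table(table)
  map <- as_tibble(map)
  stopifnot(all(c("proteoform_id", "unique_protein_id") %in% names(map)))
  target <- map$unique_protein_id[match(table$protein_id, map$proteoform_id)]
  target[is.na(target)] <- table$protein_id[is.na(target)]
  merged <- dplyr::summarise(
    dplyr::group_by(
      dplyr::mutate(table, protein_id = target),
      .data$protein_id, .data$sample_id, .data$role, .data$replicate
    ),
    intensity = if (all(is.na(.data$intensity))) NA_real_ else
      sum(.data$intensity, na.rm = TRUE),
    min_pep = min(.data$min_pep),
    unique_peptides = sum(.data$unique_peptides),
    only_by_site = all(.data$only_by_site),
    .groups = "drop"
  )
  merged
}

#' Fit the spike-in calibration curve
#'
#' Ordinary least-squares regression of log10(known amount, fmol) on
#' log10(measured intensity) over the spike-in standards detected in one
#' biological replicate; standards below the detection limit are excluded.
#' The fitted line converts any intensity of that replicate to an absolute
#' molar amount.
#'
#' @param spike a `SpikeTable` (`standard_id`, `known_amount` in fmol).
#' @param table a long-form intensity table containing the standards' rows.
#' @param replicate which biological replicate to calibrate.
#' @return a `calibration_curve` list: `replicate_id`, `slope`, `intercept`
#'   (log10 fmol), `r_squared`, `n_points`.
#' @export
fit_calibration <- function(spike, table, replicate) {
  obs <- dplyr::filter(table, .data$protein_id %in% spike$standard_id,
                       .data$replicate == !!replicate,
                       !is.na(.data$intensity))
  if (nrow(obs) < 2L) {
    stop(sprintf("calibration error: %d detected standard(s) in replicate %s (need >= 2)",
                 nrow(obs), replicate), call. = FALSE)
  }
  obs <- dplyr::left_join(obs, spike, by = c(protein_id = "standard_id"))
  fit <- stats::lm(log10(known_amount) ~ log10(intensity), data = obs)
  # summary.lm warns on exactly collinear (noise-free) points; r2 is still 1
  r2 <- suppressWarnings(summary(fit)$r.squared)
  structure(
    list(replicate_id = replicate,
         slope = unname(stats::coef(fit)[2]),
         intercept = unname(stats::coef(fit)[1]),
         r_squared = r2,
         n_points = nrow(obs)),
    class = "calibration_curve"
  )
}

#' @rdname fit_calibration
#' @return `fit_calibrations()` returns a tibble with one row per replicate
#'   present in the table.
#' @export
fit_calibrations <- function(spike, table) {
  reps <- sort(unique(table$replicate))
  dplyr::bind_rows(lapply(reps, function(r) {
    cv <- fit_calibration(spike, table, r)
    tibble(replicate = r, slope = cv$slope, intercept = cv$intercept,
           r_squared = cv$r_squared, n_points = cv$n_points)
  }))
}

#' @export
print.calibration_curve <- function(x, ...) {
  cat(sprintf(
    "<calibration_curve> replicate %s: log10(fmol) = %.4f x log10(I) %+.4f  (r2 = %.4f, n = %d)\n",
    format(x$replicate_id), x$slope, x$intercept, x$r_squared, x$n_points))
  invisible(x)
}

#' Convert intensities to absolute concentrations
#'
#' Applies each replicate's calibration line to the nuclear and cytosolic
#' intensities: `amount_fmol = 10^(slope * log10(intensity) + intercept)`,
#' then divides by the compartment volume to obtain mol/L
#' (`fmol / nl = 1e-6 mol/L`). Missing intensities give missing
#' concentrations; spike-in standards are not converted.
#'
#' @param table a filtered, merged intensity table (fractionation roles).
#' @param curves a tibble from [fit_calibrations()] (or a single
#'   `calibration_curve`).
#' @param config a [run_config()] providing the compartment volumes.
#' @param spike optional `SpikeTable`; its ids are dropped from the output.
#' @return a tibble `protein_id`, `replicate`, `compartment`, `amount_fmol`,
#'   `concentration` (mol/L).
#' @export
estimate_concentrations <- function(table, curves, config = run_config(),
                                    spike = NULL) {
  if (inherits(curves, "calibration_curve")) {
    curves <- tibble(replicate = curves$replicate_id, slope = curves$slope,
                     intercept = curves$intercept,
                     r_squared = curves$r_squared, n_points = curves$n_points)
  }
  frac <- dplyr::filter(table, .data$role %in% c("nuclear", "cytosolic"))
  if (!is.null(spike)) {
    frac <- dplyr::filter(frac, !.data$protein_id %in% spike$standard_id)
  }
  unknown <- setdiff(unique(frac$replicate), curves$replicate)
  if (length(unknown)) {
    stop(sprintf("no calibration curve for replicate(s): %s",
                 paste(unknown, collapse = ", ")), call. = FALSE)
  }
  frac <- dplyr::left_join(frac, curves[c("replicate", "slope", "intercept")],
                           by = "replicate")
  volume_nl <- ifelse(frac$role == "nuclear",
                      config$volumes$nucleus, config$volumes$cytosol)
  amount <- 10^(frac$slope * log10(frac$intensity) + frac$intercept)
  tibble(
    protein_id = frac$protein_id,
    replicate = frac$replicate,
    compartment = ifelse(frac$role == "nuclear", "nucleus", "cytosol"),
    amount_fmol = amount,
    concentration = amount * 1e-6 / volume_nl
  )
}

#' Compute N:C partition coefficients
#'
#' Averages per-replicate concentrations within each compartment (arithmetic
#' mean on the linear scale by default; replicates where the protein was not
#' detected do not contribute), then forms the nuclear-to-cytosolic ratio
#' `nc_ratio = conc_nuc / conc_cyt` and its log10 for proteins quantified in
#' both compartments. Proteins quantified in a single compartment are
#' reported with status `nuc_only` / `cyt_only` and no finite ratio.
#'
#' @param concentrations output of [estimate_concentrations()], or any tibble
#'   with `protein_id`, `compartment`, `concentration` (and optionally
#'   `replicate`).
#' @param config a [run_config()]; `config$averaging` selects arithmetic or
#'   geometric replicate averaging, `config$pseudo_ratio` enables
#'   detection-limit substitution for censored ratios.
#' @return a `PartitionRecord` tibble: `protein_id`, `conc_nuc`, `conc_cyt`
#'   (mol/L), `nc_ratio`, `log10_nc`, `status`, `flagged`, `kept_override`.
#' @export
compute_partition <- function(concentrations, config = run_config()) {
  avg <- switch(config$averaging,
    arithmetic = function(x) mean(x),
    geometric = function(x) exp(mean(log(x)))
  )
  per <- dplyr::summarise(
    dplyr::group_by(concentrations, .data$protein_id, .data$compartment),
    concentration = avg(.data$concentration[!is.na(.data$concentration)]),
    .groups = "drop"
  )
  wide <- tidyr::pivot_wider(per, names_from = "compartment",
                             values_from = "concentration")
  for (cmp in c("nucleus", "cytosol")) {
    if (!cmp %in% names(wide)) wide[[cmp]] <- NA_real_
  }
  conc_nuc <- wide$nucleus
  conc_cyt <- wide$cytosol
  status <- dplyr::case_when(
    !is.na(conc_nuc) & !is.na(conc_cyt) ~ "both",
    !is.na(conc_nuc) ~ "nuc_only",
    TRUE ~ "cyt_only"
  )
  nc <- ifelse(status == "both", conc_nuc / conc_cyt, NA_real_)
  if (isTRUE(config$pseudo_ratio)) {
    floor_nuc <- min(conc_nuc, na.rm = TRUE)
    floor_cyt <- min(conc_cyt, na.rm = TRUE)
    nc[status == "nuc_only"] <- conc_nuc[status == "nuc_only"] / floor_cyt
    nc[status == "cyt_only"] <- floor_nuc / conc_cyt[status == "cyt_only"]
  }
  tibble(
    protein_id = wide$protein_id,
    conc_nuc = conc_nuc,
    conc_cyt = conc_cyt,
    nc_ratio = nc,
    log10_nc = log10(nc),
    status = status,
    flagged = FALSE,
    kept_override = FALSE
  )
}

#' Apply contaminant flags with a manual keep list
#'
#' Proteins flagged as possibly not being cytosolic or intranuclear are
#' removed from the partition list unless they appear on the manually curated
#' keep list. The bookkeeping identity `flagged = removed + kept` holds on
#' every input.
#'
#' @param records a partition-record tibble.
#' @param flags character vector of flagged protein ids.
#' @param keeplist character vector of flagged ids to retain.
#' @return a list: `records` (surviving records, with `flagged` and
#'   `kept_override` set), `counts` (named: `flagged`, `removed`, `kept`,
#'   `keep_not_flagged`).
#' @export
apply_contaminant_flags <- function(records, flags, keeplist = character()) {
  flags <- unique(as.character(flags))
  keeplist <- unique(as.character(keeplist))
  present <- intersect(flags, records$protein_id)
  removed <- setdiff(present, keeplist)
  kept <- intersect(present, keeplist)
  stray <- setdiff(keeplist, flags)
  if (length(stray)) {
    warning(sprintf("%d keep-list entr%s not among the flags",
                    length(stray), if (length(stray) == 1L) "y is" else "ies are"),
            call. = FALSE)
  }
  out <- dplyr::mutate(
    records,
    flagged = .data$protein_id %in% present,
    kept_override = .data$protein_id %in% kept
  )
  out <- dplyr::filter(out, !.data$protein_id %in% removed)
  list(
    records = out,
    counts = c(flagged = length(present), removed = length(removed),
               kept = length(kept), keep_not_flagged = length(stray))
  )
}
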