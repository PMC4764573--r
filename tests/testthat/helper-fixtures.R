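# Shared fixtures and the independent brute-force category oracle.

# a minimal long-form intensity table built row by row
make_intensity_table <- function(protein_id, sample_id, role, replicate,
                                 intensity, min_pep = 1e-4,
                                 unique_peptides = 5L, only_by_site = FALSE) {
  tibble::tibble(
    protein_id = protein_id,
    sample_id = sample_id,
    role = role,
    replicate = as.integer(replicate),
    intensity = intensity,
    min_pep = min_pep,
    unique_peptides = as.integer(unique_peptides),
    only_by_site = only_by_site
  )
}

# truth table holding exactly the supplied concentrations, no binding
make_marker_truth <- function(ids, conc_nuc, conc_cyt) {
  tibble::tibble(
    protein_id = ids,
    true_conc_nuc = conc_nuc,
    true_conc_cyt = conc_cyt,
    cargo_strength = 0,
    background_binding = 1e-4,
    is_contaminant = FALSE,
    n_proteoforms = 1L,
    localisation = "shared",
    stratum = "nonbinder"
  )
}

noise_free_params <- function(...) {
  simulation_params(noise_sd_log10 = 0, detection_limit = 0,
                    pep_fail_rate = 0, site_flag_rate = 0,
                    single_peptide_rate = 0, proteoform_rate = 0, ...)
}

# Brute-force re-statement of the category rules, one protein at a time,
# written directly from the rule text and kept independent of the package's
# vectorised implementation.
oracle_category <- function(score, thr, machinery = NULL) {
  if (!is.null(machinery) && score$protein_id %in% names(machinery)) {
    return(unname(machinery[[score$protein_id]]))
  }
  det <- strsplit(score$detected_in, ",", fixed = TRUE)[[1]]
  stim <- score$ran_stimulation
  enr <- score$input_enrichment
  mf <- score$molar_fraction_bound
  mf_in <- score$molar_fraction_input
  ok <- function(x, gate) !is.na(x) && x >= gate
  in_plus <- "bait_plus_ran" %in% det

  if (in_plus && ok(stim, thr$a1$min_stimulation) &&
      ok(enr, thr$a1$min_enrichment) && ok(mf, thr$a1$min_molar_fraction)) {
    return("A1")
  }
  if (in_plus && ok(enr, thr$a2$min_enrichment) &&
      ok(stim, thr$a2$min_stimulation_relaxed)) {
    return("A2")
  }
  if (in_plus) {
    r <- thr$b$relax_factor
    gates <- c(ok(stim, thr$a1$min_stimulation),
               ok(enr, thr$a1$min_enrichment),
               ok(mf, thr$a1$min_molar_fraction))
    relaxed <- c(ok(stim, thr$a1$min_stimulation * r),
                 ok(enr, thr$a1$min_enrichment * r),
                 ok(mf, thr$a1$min_molar_fraction * r))
    for (i in 1:3) {
      others <- setdiff(1:3, i)
      if (all(gates[others]) && relaxed[i]) return("B")
    }
  }
  if (identical(det, "bait_plus_ran") && !ok(mf, thr$a1$min_molar_fraction)) {
    return("low_abundant")
  }
  if ("input" %in% det && ok(mf_in, thr$nonbinder$min_input_molar_fraction) &&
      !is.na(enr) && enr <= thr$nonbinder$max_enrichment) {
    return("non_binder")
  }
  "ambiguous"
}

# random score tables for oracle-equivalence checks
random_scores <- function(n) {
  pattern <- sample(c("bait_plus_ran", "input,bait_plus_ran",
                      "input,bait_minus_ran,bait_plus_ran",
                      "bait_minus_ran,bait_plus_ran"), n, replace = TRUE)
  tibble::tibble(
    protein_id = sprintf("R%03d", seq_len(n)),
    molar_fraction_bound = 10^stats::runif(n, -7, -1),
    molar_fraction_input = ifelse(grepl("input", pattern),
                                  10^stats::runif(n, -7, -1), NA_real_),
    input_enrichment = 10^stats::runif(n, -2, 3.5),
    ran_stimulation = 10^stats::runif(n, -1, 4),
    detected_in = pattern
  )
}
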