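# Scoring of RanGTP-dependent CRM1 binders from an affinity-chromatography
# intensity table: molar fractions, enrichment from input, RanGTP-stimulation
# with conservative baseline imputation, and rule-based categories.

#' Molar fractions within a sample
#'
#' A protein's molar fraction is its iBAQ intensity divided by the summed
#' iBAQ intensities of all proteins detected in the same sample; iBAQ is
#' proportional to molar amount, so fractions are mole fractions of the
#' detectable proteome. Missing intensities give missing fractions.
#'
#' @param intensity numeric vector of one sample's intensities (NA =
#'   undetected).
#' @return numeric vector of fractions summing to 1 over detected entries.
#' @export
compute_molar_fractions <- function(intensity) {
  if (!length(intensity) || all(is.na(intensity))) {
    stop("cannot compute molar fractions: no detected protein in sample",
         call. = FALSE)
  }
  intensity / sum(intensity, na.rm = TRUE)
}

#' Baseline intensity for detectability
#'
#' The conservative stand-in used when a protein was not identified in the
#' input or RanGTP-free sample: the median intensity of the `k` least
#' abundant detected proteins of that sample (all of them, if fewer than `k`
#' were detected). Ties are broken by a stable order on (intensity, id), so
#' the value is deterministic.
#'
#' @param intensity numeric vector of one sample's intensities (NA =
#'   undetected).
#' @param k window size; the study value is 30.
#' @param protein_id optional ids used only for deterministic tie-breaking.
#' @return the baseline intensity (a scalar).
#' @export
impute_baseline <- function(intensity, k = 30L, protein_id = NULL) {
  if (k < 1) abort_arg("`k` must be >= 1")
  keep <- !is.na(intensity)
  if (!any(keep)) {
    stop("cannot impute baseline: no detected protein in sample", call. = FALSE)
  }
  x <- intensity[keep]
  id <- if (is.null(protein_id)) as.character(seq_along(intensity))[keep] else
    as.character(protein_id)[keep]
  ord <- order(x, id)
  lowest <- x[ord][seq_len(min(k, length(x)))]
  stats::median(lowest)
}

#' Enrichment from input
#'
#' The ratio of a protein's molar fraction in the RanGTP-containing bait
#' eluate to its molar fraction in the starting extract. When the protein was
#' not detected in the input, the denominator is the baseline-derived input
#' fraction and the value is a lower-bound estimate (`is_estimate = TRUE`).
#'
#' @param fraction_bound molar fraction in the `bait_plus_ran` sample (must
#'   be present: undetected proteins are not scored).
#' @param fraction_input molar fraction in the input sample (NA if
#'   undetected).
#' @param baseline_input_fraction baseline intensity of the input sample
#'   divided by its summed detected intensity.
#' @return a list with `value` and `is_estimate` (vectorised over inputs).
#' @export
compute_enrichment <- function(fraction_bound, fraction_input,
                               baseline_input_fraction) {
  if (any(is.na(fraction_bound))) {
    abort_arg("protein undetected in bait_plus_ran is not scored")
  }
  est <- is.na(fraction_input)
  denom <- ifelse(est, baseline_input_fraction, fraction_input)
  list(value = fraction_bound / denom, is_estimate = est)
}

#' RanGTP-stimulation of CRM1 binding
#'
#' The ratio of a protein's iBAQ intensity in the RanGTP-containing eluate to
#' its intensity in the RanGTP-free eluate — the signature of a genuine
#' exportin-cargo interaction. When the protein was not detected without
#' RanGTP, the denominator is that sample's baseline intensity and the value
#' is a lower-bound estimate.
#'
#' @param intensity_plus intensity in `bait_plus_ran` (must be present).
#' @param intensity_minus intensity in `bait_minus_ran` (NA if undetected).
#' @param baseline_minus baseline intensity of the `bait_minus_ran` sample.
#' @return a list with `value` and `is_estimate` (vectorised over inputs).
#' @export
compute_stimulation <- function(intensity_plus, intensity_minus,
                                baseline_minus) {
  if (any(is.na(intensity_plus))) {
    abort_arg("protein undetected in bait_plus_ran is not scored")
  }
  est <- is.na(intensity_minus)
  denom <- ifelse(est, baseline_minus, intensity_minus)
  list(value = intensity_plus / denom, is_estimate = est)
}

#' Assign cargo categories
#'
#' First-match ordered rules over the three scores. Transport-machinery
#' proteins receive their machinery class (NUPs, NTRs, NPC, CRM1_cofactor)
#' regardless of scores. Otherwise:
#'
#' * `A1` — RanGTP-stimulation, input enrichment and bound molar fraction all
#'   at or above the strict gates (frog profile: 500-fold, 3-fold, 1e-4);
#' * `A2` — enrichment at or above 100-fold with a relaxed stimulation gate
#'   (captures binders like snurportin that bind strongly even without
#'   RanGTP);
#' * `B` — the A1 rule with exactly one criterion relaxed by the configured
#'   factor;
#' * `low_abundant` — detected only in the RanGTP eluate, below the A
#'   abundance gate;
#' * `non_binder` — present in the input above the abundance floor but
#'   depleted from the eluate (enrichment at or below the ceiling);
#' * `ambiguous` — everything else.
#'
#' @param scores a tibble with columns `protein_id`,
#'   `molar_fraction_bound`, `molar_fraction_input`, `input_enrichment`,
#'   `ran_stimulation`, `detected_in` (comma-separated subset of
#'   `input,bait_minus_ran,bait_plus_ran`).
#' @param thresholds a [category_thresholds()] list.
#' @param machinery named character vector mapping protein ids to machinery
#'   classes; unknown classes raise an error.
#' @return character vector of categories, aligned with `scores`.
#' @export
assign_category <- function(scores, thresholds = category_thresholds(),
                            machinery = NULL) {
  n <- nrow(scores)
  mf <- scores$molar_fraction_bound
  enr <- scores$input_enrichment
  stim <- scores$ran_stimulation
  mf_in <- scores$molar_fraction_input
  det <- scores$detected_in

  a1 <- thresholds$a1
  relax <- thresholds$b$relax_factor
  in_plus <- grepl("bait_plus_ran", det)
  only_plus <- det == "bait_plus_ran"

  ge <- function(x, gate) !is.na(x) & x >= gate
  pass_stim <- ge(stim, a1$min_stimulation)
  pass_enr <- ge(enr, a1$min_enrichment)
  pass_mf <- ge(mf, a1$min_molar_fraction)
  relaxed_stim <- ge(stim, a1$min_stimulation * relax)
  relaxed_enr <- ge(enr, a1$min_enrichment * relax)
  relaxed_mf <- ge(mf, a1$min_molar_fraction * relax)

  is_a1 <- in_plus & pass_stim & pass_enr & pass_mf
  is_a2 <- in_plus & ge(enr, thresholds$a2$min_enrichment) &
    ge(stim, thresholds$a2$min_stimulation_relaxed)
  is_b <- in_plus & (
    (relaxed_stim & pass_enr & pass_mf) |
    (pass_stim & relaxed_enr & pass_mf) |
    (pass_stim & pass_enr & relaxed_mf)
  )
  is_low <- only_plus & !pass_mf
  nb <- thresholds$nonbinder
  in_input <- grepl("input", det)
  is_nonbinder <- in_input & ge(mf_in, nb$min_input_molar_fraction) &
    !is.na(enr) & enr <= nb$max_enrichment

  category <- rep("ambiguous", n)
  category[is_nonbinder] <- "non_binder"
  category[is_low] <- "low_abundant"
  category[is_b] <- "B"
  category[is_a2] <- "A2"
  category[is_a1] <- "A1"

  if (!is.null(machinery) && length(machinery)) {
    valid <- c("NUPs", "NTRs", "NPC", "CRM1_cofactor")
    bad <- setdiff(unique(machinery), valid)
    if (length(bad)) {
      abort_arg(sprintf("unknown machinery class(es): %s",
                        paste(bad, collapse = ", ")))
    }
    hit <- match(scores$protein_id, names(machinery))
    category[!is.na(hit)] <- unname(machinery[hit[!is.na(hit)]])
  }
  category
}

#' Score and classify a full affinity experiment
#'
#' Runs the complete cargo workflow on an affinity intensity table holding
#' one sample each of the roles `input`, `bait_minus_ran` and
#' `bait_plus_ran`: molar fractions per sample, baseline imputation for
#' proteins missing from the input or RanGTP-free sample, enrichment and
#' stimulation scores, and category assignment. Every protein detected in the
#' RanGTP eluate is scored; proteins detected only elsewhere are classified
#' `non_binder` when they are abundant in the input (molar fraction at or
#' above the floor) and their baseline-bound upper-bound enrichment is at or
#' below the depletion ceiling, else `ambiguous`.
#'
#' @param table an affinity intensity table (already filtered with
#'   `filter_records(mode = "cargo")` if desired).
#' @param config a [run_config()] (thresholds and baseline window `k`).
#' @param machinery optional named vector of machinery classes.
#' @return a list: `scores` (a `CargoScore` tibble) and `census` (counts per
#'   category).
#' @export
classify_experiment <- function(table, config = run_config(),
                                machinery = NULL) {
  validate_intensity_table(table)
  roles <- c("input", "bait_minus_ran", "bait_plus_ran")
  have <- intersect(roles, unique(table$role))
  if (length(have) < length(roles)) {
    abort_arg(sprintf("missing sample role(s): %s",
                      paste(setdiff(roles, have), collapse = ", ")))
  }
  k <- config$k_baseline
  get_sample <- function(role) {
    s <- dplyr::filter(table, .data$role == !!role)
    s[match(sort(unique(table$protein_id)), s$protein_id), ]
  }
  ids <- sort(unique(table$protein_id))
  inp <- get_sample("input")
  minus <- get_sample("bait_minus_ran")
  plus <- get_sample("bait_plus_ran")

  frac_in <- compute_molar_fractions(inp$intensity)
  frac_plus <- compute_molar_fractions(plus$intensity)
  base_in <- impute_baseline(inp$intensity, k, inp$protein_id)
  base_minus <- impute_baseline(minus$intensity, k, minus$protein_id)
  base_in_frac <- base_in / sum(inp$intensity, na.rm = TRUE)

  detected_in <- vapply(seq_along(ids), function(i) {
    paste(roles[c(!is.na(inp$intensity[i]), !is.na(minus$intensity[i]),
                  !is.na(plus$intensity[i]))], collapse = ",")
  }, character(1))

  scored <- !is.na(plus$intensity)
  enrichment <- rep(NA_real_, length(ids))
  stim <- rep(NA_real_, length(ids))
  enr_est <- rep(NA, length(ids))
  stim_est <- rep(NA, length(ids))
  if (any(scored)) {
    e <- compute_enrichment(frac_plus[scored], frac_in[scored], base_in_frac)
    s <- compute_stimulation(plus$intensity[scored], minus$intensity[scored],
                             base_minus)
    enrichment[scored] <- e$value
    enr_est[scored] <- e$is_estimate
    stim[scored] <- s$value
    stim_est[scored] <- s$is_estimate
  }

  scores <- tibble(
    protein_id = ids,
    molar_fraction_bound = frac_plus,
    molar_fraction_input = frac_in,
    input_enrichment = enrichment,
    ran_stimulation = stim,
    enrichment_is_bound_estimate = enr_est,
    stimulation_is_bound_estimate = stim_est,
    detected_in = detected_in
  )
  scores <- dplyr::filter(scores, nzchar(.data$detected_in))

  category <- assign_category(scores, config$thresholds, machinery)

  # unscored proteins (absent from the RanGTP eluate): depletion rule using
  # the baseline-bound fraction as an upper bound on their enrichment
  unscored <- is.na(scores$ran_stimulation)
  if (any(unscored)) {
    base_plus <- impute_baseline(plus$intensity, k, plus$protein_id)
    base_plus_frac <- base_plus / sum(plus$intensity, na.rm = TRUE)
    nb <- config$thresholds$nonbinder
    upper_enr <- base_plus_frac / scores$molar_fraction_input[unscored]
    abundant <- !is.na(scores$molar_fraction_input[unscored]) &
      scores$molar_fraction_input[unscored] >= nb$min_input_molar_fraction
    category[unscored] <- ifelse(
      abundant & !is.na(upper_enr) & upper_enr <= nb$max_enrichment,
      "non_binder", "ambiguous")
    # machinery override still wins
    if (!is.null(machinery) && length(machinery)) {
      hit <- match(scores$protein_id[unscored], names(machinery))
      category[unscored][!is.na(hit)] <- unname(machinery[hit[!is.na(hit)]])
    }
  }
  scores$category <- category

  census <- dplyr::count(scores, .data$category, name = "n")
  list(scores = scores, census = census)
}
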