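# Synthetic-data generator: ground-truth proteomes and simulated intensity
# tables for the two experiments (compartment fractionation; CRM1 affinity
# chromatography), so that every downstream stage can be tested against a
# known truth.

#' Simulation parameters
#'
#' Observation-model and design constants for the synthetic experiments.
#'
#' The defaults emulate the oocyte study conditions: true total abundances
#' log-uniform over 5 orders of magnitude (quantitation in the study was
#' reliable over that range), multiplicative log-normal intensity noise with
#' `noise_sd_log10 = 0.18` (so that naive single-replicate recovery error
#' stays on the reported factor-of-about-two scale), hard left-censoring at a
#' detection limit, and compartment volumes of 50 nl (nucleus) and 500 nl
#' (yolk-free cytosol).
#'
#' @param n_proteins number of simulated proteins.
#' @param noise_sd_log10 standard deviation (log10 units) of the
#'   multiplicative intensity noise; `>= 0`.
#' @param detection_limit intensities below this value are reported missing
#'   (arbitrary units); `>= 0`.
#' @param response_factor intensity units per fmol of protein.
#' @param volumes named list, compartment volumes in nl.
#' @param conc_range length-2 numeric, range (mol/L) of the log-uniform total
#'   concentration prior; the default spans 5 orders of magnitude.
#' @param localisation_fractions named fractions of nuclear-only,
#'   cytosolic-only and shared proteins.
#' @param cargo_fractions named fractions of the cargo strata: `strong`
#'   (clear RanGTP-stimulated binders), `weak`, `background` (RanGTP-blind
#'   binders) and `nonbinder`.
#' @param contaminant_fraction fraction of proteins flagged as possible
#'   contaminants (ER/mitochondrial co-purification analogue).
#' @param pep_fail_rate,site_flag_rate,single_peptide_rate fractions of
#'   records failing, respectively, the PEP filter, the "only identified by
#'   site" rule and the two-unique-peptides rule.
#' @param proteoform_rate Poisson rate of extra allelic proteoforms per
#'   protein (`n_proteoforms = 1 + rpois(rate)`).
#' @param seed integer RNG seed; all generators derive their streams from it.
#'
#' @return a list of class `simulation_params`.
#' @export
simulation_params <- function(n_proteins = 2000L,
                              noise_sd_log10 = 0.18,
                              detection_limit = 5e4,
                              response_factor = 1e5,
                              volumes = list(nucleus = 50, cytosol = 500),
                              conc_range = c(1e-9, 1e-4),
                              localisation_fractions = c(nuclear = 0.22,
                                                         cytosolic = 0.21,
                                                         shared = 0.57),
                              cargo_fractions = c(strong = 0.05,
                                                  weak = 0.10,
                                                  background = 0.15,
                                                  nonbinder = 0.70),
                              contaminant_fraction = 0.13,
                              pep_fail_rate = 0.02,
                              site_flag_rate = 0.02,
                              single_peptide_rate = 0.05,
                              proteoform_rate = 0.9,
                              seed = 1L) {
  assert_scalar_number(noise_sd_log10, "noise_sd_log10", 0)
  assert_scalar_number(detection_limit, "detection_limit", 0)
  assert_scalar_number(response_factor, "response_factor", 0, strict = TRUE)
  assert_scalar_number(volumes$nucleus, "volumes$nucleus", 0, strict = TRUE)
  assert_scalar_number(volumes$cytosol, "volumes$cytosol", 0, strict = TRUE)
  stopifnot(length(conc_range) == 2L, all(conc_range > 0),
            conc_range[1] < conc_range[2])
  structure(
    list(n_proteins = as.integer(n_proteins),
         noise_sd_log10 = noise_sd_log10,
         detection_limit = detection_limit,
         response_factor = response_factor,
         volumes = volumes,
         conc_range = conc_range,
         localisation_fractions = localisation_fractions,
         cargo_fractions = cargo_fractions,
         contaminant_fraction = contaminant_fraction,
         pep_fail_rate = pep_fail_rate,
         site_flag_rate = site_flag_rate,
         single_peptide_rate = single_peptide_rate,
         proteoform_rate = proteoform_rate,
         seed = as.integer(seed)),
    class = "simulation_params"
  )
}

#' Generate a ground-truth proteome
#'
#' Draws true per-compartment concentrations, cargo-binding parameters and
#' contaminant status for `n_proteins` proteins.
#'
#' Total concentrations are log-uniform over `params$conc_range` (5 orders of
#' magnitude by default). Localisation classes and cargo strata are allocated
#' deterministically by largest remainder, so exact-multiple fractions give
#' exact stratum counts; labels are then assigned to proteins in a seeded
#' random order. The `strong` stratum emulates clear-cut, A-grade binders —
#' the abundant (upper two orders of the prior), strongly RanGTP-stimulated
#' reference class the category gates are calibrated on; rare strong binders
#' belong in the `low_abundant` outcome and are not part of this stratum.
#' Non-binders have `cargo_strength = 0` by construction.
#'
#' @param n_proteins number of proteins (overrides `params$n_proteins`).
#' @param params a [simulation_params()] list.
#' @return a `TruthTable` tibble with columns `protein_id`, `true_conc_nuc`,
#'   `true_conc_cyt` (mol/L), `cargo_strength`, `background_binding`,
#'   `is_contaminant`, `n_proteoforms`, plus the generative labels
#'   `localisation` and `stratum`.
#' @export
generate_ground_truth <- function(n_proteins = params$n_proteins,
                                  params = simulation_params()) {
  if (!is.numeric(n_proteins) || length(n_proteins) != 1L || n_proteins < 1) {
    abort_arg("`n_proteins` must be a positive integer")
  }
  n <- as.integer(n_proteins)
  withr::with_seed(params$seed, {
    id <- sprintf("P%05d", seq_len(n))
    conc_total <- rlogunif(n, params$conc_range[1], params$conc_range[2])

    loc_counts <- allocate_counts(n, params$localisation_fractions)
    localisation <- rep(names(loc_counts), loc_counts)[sample.int(n)]

    strata_counts <- allocate_counts(n, params$cargo_fractions)
    stratum <- rep(names(strata_counts), strata_counts)[sample.int(n)]

    # strong cargoes: upper two abundance orders of the prior (the clear-cut
    # binders the category gates are calibrated on are abundant proteins)
    is_strong <- stratum == "strong"
    if (any(is_strong)) {
      hi <- params$conc_range[2]
      conc_total[is_strong] <- rlogunif(sum(is_strong), hi / 1e2, hi)
    }

    # partition the total concentration between compartments
    log10_nc <- stats::rnorm(n, 0, 1.2)
    frac_nuc <- 10^log10_nc / (1 + 10^log10_nc)
    conc_nuc <- ifelse(localisation == "cytosolic", 0,
                ifelse(localisation == "nuclear", conc_total,
                       conc_total * frac_nuc))
    conc_cyt <- ifelse(localisation == "nuclear", 0,
                ifelse(localisation == "cytosolic", conc_total,
                       conc_total * (1 - frac_nuc)))

    background <- rlogunif(n, 1e-4, 1e-3)
    background[stratum == "background"] <- rlogunif(sum(stratum == "background"),
                                                    1e-3, 1e-2)
    strength <- numeric(n)
    strength[is_strong] <- rlogunif(sum(is_strong), 5, 50)
    strength[stratum == "weak"] <- rlogunif(sum(stratum == "weak"), 0.005, 0.1)

    tibble(
      protein_id = id,
      true_conc_nuc = conc_nuc,
      true_conc_cyt = conc_cyt,
      cargo_strength = strength,
      background_binding = background,
      is_contaminant = stats::runif(n) < params$contaminant_fraction,
      n_proteoforms = 1L + stats::rpois(n, params$proteoform_rate),
      localisation = localisation,
      stratum = stratum
    )
  })
}

#' Build a spike-in standard table
#'
#' Mirrors the layout of a universal protein standard (UPS2): `n_groups`
#' groups of `per_group` proteins at known molar amounts forming a geometric
#' series with constant `fold_step` between groups, spanning
#' `fold_step^(n_groups - 1)` overall.
#'
#' @param n_groups number of amount groups.
#' @param per_group proteins per group.
#' @param min_amount amount (fmol) of the lowest group.
#' @param fold_step fold difference between consecutive groups; must be > 1.
#' @return a `SpikeTable` tibble with `standard_id`, `known_amount` (fmol)
#'   and `group`.
#' @export
make_spike_standard <- function(n_groups = 6L, per_group = 8L,
                                min_amount = 0.5, fold_step = 10) {
  assert_scalar_number(n_groups, "n_groups", 1)
  assert_scalar_number(per_group, "per_group", 1)
  assert_scalar_number(min_amount, "min_amount", 0, strict = TRUE)
  if (!is.numeric(fold_step) || fold_step <= 1) {
    abort_arg("`fold_step` must be > 1")
  }
  group <- rep(seq_len(n_groups), each = per_group)
  tibble(
    standard_id = sprintf("UPS%02d", seq_along(group)),
    known_amount = min_amount * fold_step^(group - 1),
    group = as.integer(group)
  )
}

# observation model: intensity = response_factor * amount_fmol * 10^eps,
# censored below the detection limit
observe_intensity <- function(amount_fmol, params) {
  eps <- if (params$noise_sd_log10 > 0) {
    stats::rnorm(length(amount_fmol), 0, params$noise_sd_log10)
  } else {
    0
  }
  intensity <- params$response_factor * amount_fmol * 10^eps
  intensity[amount_fmol <= 0] <- NA_real_
  intensity[!is.na(intensity) & intensity < params$detection_limit] <- NA_real_
  intensity
}

# identification metadata shared by both simulated experiments; drawn per
# record set so a configurable fraction fails each filter
draw_id_metadata <- function(n, params) {
  pep_fail <- stats::runif(n) < params$pep_fail_rate
  min_pep <- 10^stats::runif(n, -5, log10(0.01))
  min_pep[pep_fail] <- stats::runif(sum(pep_fail), 0.011, 0.2)
  single <- stats::runif(n) < params$single_peptide_rate
  unique_peptides <- 2L + stats::rpois(n, 6)
  unique_peptides[single] <- 1L
  tibble(
    min_pep = min_pep,
    unique_peptides = unique_peptides,
    only_by_site = stats::runif(n) < params$site_flag_rate
  )
}

#' Simulate the fractionation experiment
#'
#' Generates proteoform-level iBAQ-like intensities for dissected nuclear and
#' cytosolic fractions over `n_replicates` biological replicates, with the
#' spike-in standards added to every sample.
#'
#' For a protein with true concentration c (mol/L) in a compartment of
#' volume V (nl), the molar amount is `c * V * 1e-9 * 1e15` fmol and the
#' observed intensity is `response_factor * amount * 10^eps` with
#' `eps ~ Normal(0, noise_sd_log10)`, censored below the detection limit.
#' A protein's compartment amount is split across its `n_proteoforms`
#' allelic forms by a symmetric Dirichlet (alpha = 2); the proteoform-to-
#' protein map is attached as attribute `"proteoform_map"`.
#'
#' @param truth a `TruthTable` from [generate_ground_truth()].
#' @param spike a `SpikeTable` from [make_spike_standard()]; `NULL` to omit
#'   standards.
#' @param params a [simulation_params()] list.
#' @param n_replicates number of biological replicates (>= 1).
#' @param expand_proteoforms if `FALSE`, one row per protein (no allelic
#'   expansion).
#' @return a long-form `IntensityTable` tibble (see [read_intensity_table()]
#'   for the column contract) with attribute `proteoform_map`.
#' @export
simulate_fraction_intensities <- function(truth, spike = make_spike_standard(),
                                          params = simulation_params(),
                                          n_replicates = 3L,
                                          expand_proteoforms = TRUE) {
  if (is.null(truth) || nrow(truth) == 0L) abort_arg("`truth` must be non-empty")
  if (!is.numeric(n_replicates) || n_replicates < 1) {
    abort_arg("`n_replicates` must be >= 1")
  }
  n_replicates <- as.integer(n_replicates)
  nl_to_fmol <- 1e-9 * 1e15  # mol/L * nl -> fmol

  withr::with_seed(params$seed + 1L, {
    # proteoform expansion: split each protein's amount by Dirichlet(2)
    if (expand_proteoforms) {
      reps <- truth$n_proteoforms
      map <- tibble(
        proteoform_id = paste0(rep(truth$protein_id, reps), ".",
                               unlist(lapply(reps, seq_len))),
        unique_protein_id = rep(truth$protein_id, reps)
      )
      g <- stats::rgamma(nrow(map), shape = 2)
      share <- g / stats::ave(g, map$unique_protein_id, FUN = sum)
    } else {
      map <- tibble(proteoform_id = truth$protein_id,
                    unique_protein_id = truth$protein_id)
      share <- rep(1, nrow(map))
    }
    idx <- match(map$unique_protein_id, truth$protein_id)
    amount_nuc <- truth$true_conc_nuc[idx] * params$volumes$nucleus *
      nl_to_fmol * share
    amount_cyt <- truth$true_conc_cyt[idx] * params$volumes$cytosol *
      nl_to_fmol * share

    meta <- list(
      nuclear = draw_id_metadata(nrow(map), params),
      cytosolic = draw_id_metadata(nrow(map), params)
    )

    out <- vector("list", 2L * n_replicates)
    k <- 0L
    for (r in seq_len(n_replicates)) {
      for (cmp in c("nuclear", "cytosolic")) {
        amount <- if (cmp == "nuclear") amount_nuc else amount_cyt
        sid <- sprintf("%s_%d", if (cmp == "nuclear") "nuc" else "cyt", r)
        rows <- tibble(
          protein_id = map$proteoform_id,
          sample_id = sid,
          role = cmp,
          replicate = r,
          intensity = observe_intensity(amount, params)
        )
        rows <- dplyr::bind_cols(rows, meta[[cmp]])
        if (!is.null(spike) && nrow(spike) > 0L) {
          srows <- tibble(
            protein_id = spike$standard_id,
            sample_id = sid,
            role = cmp,
            replicate = r,
            intensity = observe_intensity(spike$known_amount, params),
            min_pep = 1e-4,
            unique_peptides = 5L,
            only_by_site = FALSE
          )
          rows <- dplyr::bind_rows(rows, srows)
        }
        k <- k + 1L
        out[[k]] <- rows
      }
    }
    res <- dplyr::bind_rows(out)
    attr(res, "proteoform_map") <- map
    res
  })
}

#' Simulate the CRM1 affinity-chromatography experiment
#'
#' Produces three samples per protein: the starting extract (`input`,
#' proportional to total abundance), the RanGTP-free bait eluate
#' (`bait_minus_ran`, proportional to `background_binding * abundance`), and
#' the RanGTP-containing eluate (`bait_plus_ran`, proportional to
#' `(background_binding + cargo_strength) * abundance`). Noise and censoring
#' follow the same observation model as the fractionation simulation.
#'
#' @inheritParams simulate_fraction_intensities
#' @return a long-form `IntensityTable` tibble.
#' @export
simulate_affinity_experiment <- function(truth, params = simulation_params()) {
  if (is.null(truth) || nrow(truth) == 0L) abort_arg("`truth` must be non-empty")
  nl_to_fmol <- 1e-9 * 1e15
  withr::with_seed(params$seed + 2L, {
    abundance <- truth$true_conc_nuc * params$volumes$nucleus * nl_to_fmol +
      truth$true_conc_cyt * params$volumes$cytosol * nl_to_fmol
    occupancy <- list(
      input = rep(1, nrow(truth)),
      bait_minus_ran = truth$background_binding,
      bait_plus_ran = truth$background_binding + truth$cargo_strength
    )
    meta <- draw_id_metadata(nrow(truth), params)
    rows <- lapply(names(occupancy), function(smp) {
      dplyr::bind_cols(
        tibble(
          protein_id = truth$protein_id,
          sample_id = smp,
          role = smp,
          replicate = 1L,
          intensity = observe_intensity(abundance * occupancy[[smp]], params)
        ),
        meta
      )
    })
    dplyr::bind_rows(rows)
  })
}

#' @rdname simulate_fraction_intensities
#' @param table an intensity table produced with proteoform expansion.
#' @return `proteoform_map()` returns the proteoform-to-protein map attached
#'   to a simulated table.
#' @export
proteoform_map <- function(table) {
  map <- attr(table, "proteoform_map")
  if (is.null(map)) abort_arg("table carries no proteoform map")
  map
}
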