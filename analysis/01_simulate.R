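#!/usr/bin/env Rscript
# Stage 1 — simulate both experiments.
#
# Generates a 2000-protein ground-truth proteome (true nuclear and cytosolic
# concentrations, cargo-binding parameters, contaminant status), then
# simulates (i) the dissected-fraction quantitation experiment in three
# biological replicates with a UPS2-like spike-in standard and (ii) the CRM1
# affinity-chromatography experiment (input / bait without RanGTP / bait with
# RanGTP). All tables are written under results/synthetic/ as TSV, the truth
# with a truth_ column prefix so downstream stages can be scored against it.

suppressMessages(library(exportome))

seed <- 20260920L %% 100000L  # fixed run seed
out <- "results/synthetic"
dir.create(out, showWarnings = FALSE, recursive = TRUE)

params <- simulation_params(seed = seed)
truth <- generate_ground_truth(2000, params)
spike <- make_spike_standard()          # 6 groups x 8, 0.5 fmol, 10-fold steps
fractions <- simulate_fraction_intensities(truth, spike, params,
                                           n_replicates = 3)
affinity <- simulate_affinity_experiment(truth, params)

write_truth_table(truth, file.path(out, "truth.tsv"))
write_intensity_table(fractions, file.path(out, "fraction_intensities.tsv"))
write_intensity_table(affinity, file.path(out, "affinity_intensities.tsv"))
readr::write_tsv(proteoform_map(fractions),
                 file.path(out, "proteoform_map.tsv"))
readr::write_tsv(
  tibble::tibble(standard_id = spike$standard_id,
                 amount_fmol = spike$known_amount),
  file.path(out, "spike_amounts.tsv")
)

# contaminant flags come from the simulated truth; a small manual keep list
# mimics curation of genuinely intranuclear/cytosolic proteins
flags <- truth$protein_id[truth$is_contaminant]
keep <- head(flags, max(1L, round(0.035 * length(flags))))
writeLines(flags, file.path(out, "contaminant_flags.txt"))
writeLines(keep, file.path(out, "keep_list.txt"))

write_run_config(run_config(seed = seed), file.path(out, "config.yaml"))
write_run_manifest("simulate", out, seed = seed,
                   config_path = file.path(out, "config.yaml"),
                   outputs = c(truth = file.path(out, "truth.tsv")))

cat(sprintf("simulated %d proteins (%d proteoforms) | %d flagged contaminants, %d on keep list\n",
            nrow(truth), nrow(proteoform_map(fractions)), length(flags),
            length(keep)))
cat(sprintf("abundance span: %.1f orders of magnitude\n",
            log10(max(truth$true_conc_nuc + truth$true_conc_cyt) /
                  min(truth$true_conc_nuc + truth$true_conc_cyt))))
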