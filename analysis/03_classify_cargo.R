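#!/usr/bin/env Rscript
# Stage 3 — CRM1 cargo scoring and categorisation.
#
# Reads the simulated affinity-chromatography table, applies the cargo-mode
# identification filters (site flag within the RanGTP eluate, PEP, two
# unique peptides), scores every protein detected in the RanGTP eluate
# (molar fraction bound, enrichment from input, RanGTP-stimulation — with
# the conservative detectability baseline for proteins missing from the
# input or RanGTP-free sample) and assigns categories A1/A2/B/low_abundant/
# non_binder/ambiguous. Writes cargo_report.tsv and category_census.tsv and
# compares the outcome against the simulation's ground-truth strata.

suppressMessages(library(exportome))

src <- "results/synthetic"
out <- "results/cargo"
dir.create(out, showWarnings = FALSE, recursive = TRUE)
config <- read_run_config(file.path(src, "config.yaml"))

manifest <- readr::read_tsv(
  file.path(src, "affinity_intensities.tsv.manifest.tsv"),
  show_col_types = FALSE
)
aff <- read_intensity_table(file.path(src, "affinity_intensities.tsv"),
                            manifest)

filt <- filter_records(aff, config, mode = "cargo")
cat(sprintf("cargo filters removed %d protein(s)\n",
            dplyr::n_distinct(filt$log$protein_id)))

res <- classify_experiment(filt$table, config)
write_reports(cargo = res$scores, dir = out)
readr::write_tsv(res$census, file.path(out, "category_census.tsv"))
readr::write_tsv(filt$log, file.path(out, "filter_log.tsv"))
write_run_manifest("classify", out, seed = config$seed,
                   inputs = c(affinity = file.path(src, "affinity_intensities.tsv")),
                   outputs = c(cargo = file.path(out, "cargo_report.tsv")))

cat("category census:\n")
print(as.data.frame(res$census), row.names = FALSE)

truth <- read_truth_table(file.path(src, "truth.tsv"))
sc <- dplyr::left_join(res$scores, truth[c("protein_id", "stratum")],
                       by = "protein_id")
strong <- truth$protein_id[truth$stratum == "strong"]
in_ab <- sc$protein_id[sc$category %in% c("A1", "A2", "B")]
cat(sprintf("strong-cargo recovery into A/B: %.1f%% (%d of %d)\n",
            100 * mean(strong %in% in_ab), sum(strong %in% in_ab),
            length(strong)))
strong_pass <- intersect(strong, filt$table$protein_id)
cat(sprintf("  among those passing the identification filters: %.1f%% (%d of %d)\n",
            100 * mean(strong_pass %in% in_ab),
            sum(strong_pass %in% in_ab), length(strong_pass)))
cat(sprintf("background/non-binder proteins in A1: %d\n",
            sum(sc$category == "A1" &
                  sc$stratum %in% c("background", "nonbinder"), na.rm = TRUE)))
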