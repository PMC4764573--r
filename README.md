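# exportome

Spike-in-calibrated absolute protein quantitation, nucleocytoplasmic (N:C)
partitioning, and RanGTP-dependent CRM1 cargo classification from
intensity-based proteomics tables.

The package is aimed at analysts working with compartment-resolved
label-free proteomics — dissected oocyte fractions in the motivating
design — and with CRM1 (exportin 1) affinity-chromatography screens. It
implements the full downstream computation from protein-level intensity
tables to reports, plus a synthetic-data generator with known ground truth
so the whole pipeline is testable without raw mass-spectrometry data.

## What it computes

**Absolute quantitation.** Per biological replicate, the known molar
amounts of a UPS2-style spike-in standard are regressed on measured iBAQ
intensities (both log10):

    log10(amount_fmol) = a · log10(I) + b

and the fitted line converts every protein's intensity to fmol. Fixed
compartment volumes (nucleus 50 nl, yolk-free cytosol 500 nl) turn amounts
into molar concentrations, replicates are averaged, and the partition
coefficient is

    N:C = c_nuc / c_cyt

reported linearly and on the log10 scale, with proteins detected in one
compartment carried as censored (`nuc_only` / `cyt_only`). Upstream:
PEP ≤ 0.01 and "only identified by site" filters, allelic-proteoform
merging, and contaminant-flag bookkeeping with a manual keep list.

**Cargo classification.** From an input / CRM1-without-Ran / CRM1+RanGTP
experiment, each protein detected in the RanGTP eluate gets three scores —
molar fraction bound, enrichment from input (ratio of molar fractions), and
RanGTP-stimulation (ratio of bait intensities) — with a conservative
detectability baseline (median of the 30 least abundant detected proteins)
substituted for missing denominators. First-match rules assign categories:
A1 (stimulation ≥ 500-fold, enrichment ≥ 3-fold, abundant in the eluate),
A2 (enrichment ≥ 100-fold, relaxed stimulation), B (one A1 criterion
relaxed), `low_abundant`, `non_binder`, `ambiguous`, with transport
machinery (NUPs, NTRs, NPC, CRM1 cofactor) labelled separately.

## Worked example

```r
library(exportome)

# nucleophosmin-like marker: 2.3 uM nuclear, 8 nM cytoplasmic
part <- compute_partition(tibble::tibble(
  protein_id  = "nucleophosmin",
  compartment = c("nucleus", "cytosol"),
  concentration = c(2.3e-6, 8e-9)
))
part$nc_ratio          # 287.5
signif(part$nc_ratio, 1)  # 300  -> reported as a 300:1 partition coefficient
```

The full simulated workflow lives in `analysis/` as numbered stages:

```sh
Rscript analysis/01_simulate.R        # ground truth + both experiments
Rscript analysis/02_quantify.R        # calibration, concentrations, N:C
Rscript analysis/03_classify_cargo.R  # cargo scores and categories
Rscript analysis/04_summarise.R       # Venn accounting, N:C density curves
```

A run at the default settings (2000 proteins, 3 replicates, multiplicative
noise of 0.18 log10 units) prints, among other things:

```
simulated 2000 proteins (3760 proteoforms) | 260 flagged contaminants, 9 on keep list
abundance span: 5.0 orders of magnitude
contaminant bookkeeping: 254 flagged = 246 removed + 8 kept
detection: 331 nucleus-only, 753 cytosol-only, 639 both (total 1723)
strong-cargo recovery into A/B: 86.0% (86 of 100)
  among those passing the identification filters: 95.6% (86 of 90)
background/non-binder proteins in A1: 0
```

i.e. the per-replicate calibration lines recover the simulator's response,
strong simulated cargoes are recovered into categories A/B, purely
background-binding proteins never reach A1, and the detection statuses
partition the surviving proteins exactly. Stage outputs (reports, filter
logs, census, density curves, manifests) are written under `results/`.

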