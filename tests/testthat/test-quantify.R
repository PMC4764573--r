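cfg <- run_config()

test_that("partition-mode filters apply the PEP and single-compartment site rules", {
  tab <- dplyr::bind_rows(
    # high-PEP protein: removed
    make_intensity_table("highpep", c("nuc_1", "cyt_1"),
                         c("nuclear", "cytosolic"), 1, c(1e6, 1e6),
                         min_pep = 0.02),
    # site-flagged, detected in both compartments: retained
    make_intensity_table("site_both", c("nuc_1", "cyt_1"),
                         c("nuclear", "cytosolic"), 1, c(1e6, 1e6),
                         only_by_site = TRUE),
    # site-flagged, detected in one compartment: removed
    make_intensity_table("site_one", c("nuc_1", "cyt_1"),
                         c("nuclear", "cytosolic"), 1, c(1e6, NA),
                         only_by_site = TRUE),
    make_intensity_table("clean", c("nuc_1", "cyt_1"),
                         c("nuclear", "cytosolic"), 1, c(1e5, 1e5))
  )
  res <- filter_records(tab, cfg, "partition")
  kept <- unique(res$table$protein_id)
  expect_setequal(kept, c("site_both", "clean"))
  expect_equal(res$log$rule[res$log$protein_id == "highpep"], "pep")
  expect_equal(res$log$rule[res$log$protein_id == "site_one"], "site")
})

test_that("cargo-mode filters require two unique peptides and drop site flags in the RanGTP eluate", {
  tab <- dplyr::bind_rows(
    make_intensity_table("one_pep", c("input", "crm1", "crm1_ran"),
                         c("input", "bait_minus_ran", "bait_plus_ran"), 1,
                         c(1e6, 1e5, 1e7), unique_peptides = 1L),
    make_intensity_table("site_plus", c("input", "crm1", "crm1_ran"),
                         c("input", "bait_minus_ran", "bait_plus_ran"), 1,
                         c(1e6, 1e5, 1e7), only_by_site = TRUE),
    make_intensity_table("clean", c("input", "crm1", "crm1_ran"),
                         c("input", "bait_minus_ran", "bait_plus_ran"), 1,
                         c(1e6, 1e5, 1e7))
  )
  res <- filter_records(tab, cfg, "cargo")
  expect_setequal(unique(res$table$protein_id), "clean")
  expect_true("unique_peptides" %in%
                res$log$rule[res$log$protein_id == "one_pep"])
  expect_true("site_bait" %in%
                res$log$rule[res$log$protein_id == "site_plus"])
})

test_that("proteoform merging sums intensities and combines metadata conservatively", {
  tab <- dplyr::bind_rows(
    make_intensity_table("P1.1", "nuc_1", "nuclear", 1, 3e6,
                         min_pep = 1e-3, unique_peptides = 2L,
                         only_by_site = TRUE),
    make_intensity_table("P1.2", "nuc_1", "nuclear", 1, 7e6,
                         min_pep = 1e-5, unique_peptides = 3L,
                         only_by_site = FALSE),
    make_intensity_table("P2.1", "nuc_1", "nuclear", 1, NA_real_),
    make_intensity_table("P2.2", "nuc_1", "nuclear", 1, NA_real_)
  )
  map <- tibble::tibble(proteoform_id = c("P1.1", "P1.2", "P2.1", "P2.2"),
                        unique_protein_id = c("P1", "P1", "P2", "P2"))
  merged <- merge_proteoforms(tab, map)
  p1 <- merged[merged$protein_id == "P1", ]
  expect_equal(p1$intensity, 1e7)
  expect_equal(p1$min_pep, 1e-5)
  expect_equal(p1$unique_peptides, 5L)
  expect_false(p1$only_by_site)  # conjunction: one member is site-independent
  expect_true(is.na(merged$intensity[merged$protein_id == "P2"]))

  # identity map leaves values unchanged
  idmap <- tibble::tibble(proteoform_id = character(),
                          unique_protein_id = character())
  same <- merge_proteoforms(tab, idmap)
  expect_setequal(same$protein_id, tab$protein_id)
  expect_equal(sort(same$intensity), sort(tab$intensity))
})

test_that("calibration regression has the closed-form solution on exact log-linear data", {
  amounts <- c(0.5, 5, 50, 500, 5000)
  spike <- tibble::tibble(standard_id = paste0("U", 1:5),
                          known_amount = amounts)
  # identity data: intensity equals amount
  tab <- make_intensity_table(spike$standard_id, "s_1", "standard", 1, amounts)
  cv <- fit_calibration(spike, tab, 1)
  expect_equal(cv$slope, 1, tolerance = 1e-12)
  expect_equal(cv$intercept, 0, tolerance = 1e-12)
  expect_equal(cv$r_squared, 1, tolerance = 1e-12)
  expect_equal(cv$n_points, 5L)

  # intensity = 100 x amount  =>  log10(amount) = log10(I) - 2
  tab2 <- make_intensity_table(spike$standard_id, "s_1", "standard", 1,
                               100 * amounts)
  cv2 <- fit_calibration(spike, tab2, 1)
  expect_equal(cv2$slope, 1, tolerance = 1e-9)
  expect_equal(cv2$intercept, -2, tolerance = 1e-9)

  # undetected standards are excluded; fewer than two is an error
  tab3 <- tab
  tab3$intensity[2:5] <- NA
  expect_error(fit_calibration(spike, tab3, 1), "calibration error")
  expect_error(fit_calibration(spike, tab, 2), "calibration error")
})

test_that("concentration conversion follows amount / volume with the fitted line", {
  curve <- tibble::tibble(replicate = 1L, slope = 1, intercept = 0,
                          r_squared = 1, n_points = 5L)
  tab <- make_intensity_table("P1", "nuc_1", "nuclear", 1, 50)
  conc <- estimate_concentrations(tab, curve, cfg)
  # 50 fmol in 50 nl is 1 uM
  expect_equal(conc$amount_fmol, 50)
  expect_equal(conc$concentration, 1e-6)

  # identity curve: intensity 10 is 10 fmol
  tab10 <- make_intensity_table("P1", "cyt_1", "cytosolic", 1, 10)
  expect_equal(estimate_concentrations(tab10, curve, cfg)$amount_fmol, 10)

  # doubling both volumes halves every concentration
  cfg2 <- run_config(volumes = list(nucleus = 100, cytosol = 1000))
  expect_equal(estimate_concentrations(tab, curve, cfg2)$concentration, 5e-7)

  # unknown replicate is a lookup error
  tab_r2 <- make_intensity_table("P1", "nuc_2", "nuclear", 2, 50)
  expect_error(estimate_concentrations(tab_r2, curve, cfg), "replicate")
})

test_that("partition records reproduce the marker worked examples", {
  conc <- tibble::tibble(
    protein_id = rep(c("nucleophosmin", "gelsolin", "balanced"), each = 2),
    compartment = rep(c("nucleus", "cytosol"), 3),
    concentration = c(2.3e-6, 8e-9, 0.01e-6, 4e-6, 5e-7, 5e-7)
  )
  part <- compute_partition(conc, cfg)
  npm <- part[part$protein_id == "nucleophosmin", ]
  expect_equal(npm$nc_ratio, 287.5)
  expect_equal(signif(npm$nc_ratio, 1), 300)
  gsn <- part[part$protein_id == "gelsolin", ]
  expect_equal(gsn$nc_ratio, 1 / 400)
  bal <- part[part$protein_id == "balanced", ]
  expect_equal(bal$nc_ratio, 1)
  expect_equal(bal$log10_nc, 0)
})

test_that("replicate averaging, censoring status and ratio antisymmetry behave as specified", {
  conc <- tibble::tibble(
    protein_id = c("a", "a", "a", "b", "c"),
    replicate = c(1L, 2L, 1L, 1L, 1L),
    compartment = c("nucleus", "nucleus", "cytosol", "nucleus", "cytosol"),
    concentration = c(2e-6, 4e-6, 1e-6, 1e-7, NA)
  )
  part <- compute_partition(conc, cfg)
  a <- part[part$protein_id == "a", ]
  expect_equal(a$conc_nuc, 3e-6)  # arithmetic mean over detected replicates
  expect_equal(a$nc_ratio, 3)
  expect_equal(part$status[part$protein_id == "b"], "nuc_only")
  expect_true(is.na(part$nc_ratio[part$protein_id == "b"]))
  expect_equal(part$status[part$protein_id == "c"], "cyt_only")

  # geometric option
  geo <- compute_partition(conc, run_config(averaging = "geometric"))
  expect_equal(geo$conc_nuc[geo$protein_id == "a"], sqrt(2e-6 * 4e-6))

  # antisymmetry: swapping compartment labels inverts every finite ratio
  withr::with_seed(303, {
    rnd <- tibble::tibble(
      protein_id = rep(sprintf("p%02d", 1:30), each = 2),
      compartment = rep(c("nucleus", "cytosol"), 30),
      concentration = 10^stats::runif(60, -9, -4)
    )
  })
  fwd <- compute_partition(rnd, cfg)
  swapped <- dplyr::mutate(rnd, compartment = ifelse(compartment == "nucleus",
                                                     "cytosol", "nucleus"))
  rev <- compute_partition(swapped, cfg)
  rev <- rev[match(fwd$protein_id, rev$protein_id), ]
  expect_equal(rev$nc_ratio, 1 / fwd$nc_ratio)

  # bookkeeping: the statuses partition the surviving proteins
  vc <- venn_counts(part)
  expect_equal(vc$total, dplyr::n_distinct(conc$protein_id))
})

test_that("contaminant flags obey the removed/kept bookkeeping identity", {
  records <- compute_partition(tibble::tibble(
    protein_id = rep(letters[1:6], each = 2),
    compartment = rep(c("nucleus", "cytosol"), 6),
    concentration = 1e-6
  ))
  res <- apply_contaminant_flags(records, flags = c("a", "b", "c"),
                                 keeplist = "c")
  expect_setequal(res$records$protein_id, c("c", "d", "e", "f"))
  expect_true(res$records$kept_override[res$records$protein_id == "c"])
  expect_equal(unname(res$counts[c("flagged", "removed", "kept")]),
               c(3, 2, 1))
  expect_equal(res$counts[["flagged"]],
               res$counts[["removed"]] + res$counts[["kept"]])

  # empty flags: all-zero counts, nothing removed
  res0 <- apply_contaminant_flags(records, character())
  expect_equal(unname(res0$counts[c("flagged", "removed", "kept")]),
               c(0, 0, 0))
  expect_equal(nrow(res0$records), nrow(records))

  # keep-list entries that were never flagged are warned about and counted
  expect_warning(
    res1 <- apply_contaminant_flags(records, flags = "a",
                                    keeplist = c("a", "zzz")),
    "not among the flags"
  )
  expect_equal(res1$counts[["keep_not_flagged"]], 1)

  # the identity holds on random instances
  withr::with_seed(304, {
    for (i in 1:20) {
      fl <- sample(records$protein_id, sample(0:6, 1))
      kp <- sample(records$protein_id, sample(0:3, 1))
      r <- suppressWarnings(apply_contaminant_flags(records, fl, kp))
      expect_equal(r$counts[["flagged"]],
                   r$counts[["removed"]] + r$counts[["kept"]])
    }
  })
})
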