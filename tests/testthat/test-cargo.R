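thr <- category_thresholds()

test_that("molar fractions normalise over detected proteins", {
  expect_equal(compute_molar_fractions(c(1, 2, 7)), c(0.1, 0.2, 0.7))
  expect_equal(compute_molar_fractions(5), 1)
  x <- c(1e6, NA, 3e5, 2e9, NA, 4e4)
  f <- compute_molar_fractions(x)
  expect_equal(sum(f, na.rm = TRUE), 1, tolerance = 1e-12)
  expect_true(all(is.na(f[is.na(x)])))
  expect_error(compute_molar_fractions(c(NA_real_, NA_real_)), "no detected")
})

test_that("baseline imputation is the median of the k least abundant proteins", {
  expect_equal(impute_baseline(1:40, k = 30), stats::median(1:30))
  expect_equal(impute_baseline(1:40, k = 30), 15.5)
  # fewer detected than k: median of all of them
  expect_equal(impute_baseline(c(4, 9, 1, 7, 2), k = 30),
               stats::median(c(4, 9, 1, 7, 2)))
  expect_equal(impute_baseline(c(8, 3, 5), k = 1), 3)
  # ties resolve by the stable (intensity, id) order, deterministically
  expect_equal(impute_baseline(rep(c(2, 2, 5), 20), k = 30,
                               protein_id = sprintf("p%02d", 1:60)), 2)
  expect_error(impute_baseline(rep(NA_real_, 3), 30), "no detected")

  # conservatism: baseline never exceeds the overall detected median
  withr::with_seed(401, {
    for (i in 1:25) {
      x <- 10^stats::runif(sample(5:200, 1), 2, 9)
      expect_lte(impute_baseline(x, 30), stats::median(x))
    }
  })
})

test_that("enrichment and stimulation ratios flag baseline-derived estimates", {
  e <- compute_enrichment(0.001, 0.001, 1e-6)
  expect_equal(e$value, 1)
  expect_false(e$is_estimate)
  e2 <- compute_enrichment(0.01, NA_real_, 1e-5)
  expect_equal(e2$value, 1000)
  expect_true(e2$is_estimate)
  expect_error(compute_enrichment(NA_real_, 0.1, 1e-5), "not scored")

  s <- compute_stimulation(5e9, 1e7, 1e6)
  expect_equal(s$value, 500)
  expect_false(s$is_estimate)
  s2 <- compute_stimulation(1e9, NA_real_, 1e6)
  expect_equal(s2$value, 1000)
  expect_true(s2$is_estimate)
})

test_that("category assignment honours the frog gates and machinery overrides", {
  scores <- tibble::tibble(
    protein_id = c("a1", "a2", "low", "nb", "amb", "nup"),
    molar_fraction_bound = c(1e-3, 1e-3, 1e-5, NA, 2e-5, 1e-3),
    molar_fraction_input = c(1e-4, 1e-5, NA, 1e-3, 1e-4, 1e-4),
    input_enrichment = c(5, 150, 10, 0.05, 0.5, 5),
    ran_stimulation = c(600, 10, 800, NA, 2, 700),
    detected_in = c("input,bait_minus_ran,bait_plus_ran",
                    "input,bait_plus_ran",
                    "bait_plus_ran",
                    "input,bait_minus_ran",
                    "input,bait_plus_ran",
                    "input,bait_minus_ran,bait_plus_ran")
  )
  got <- assign_category(scores, thr, machinery = c(nup = "NUPs"))
  expect_equal(got, c("A1", "A2", "low_abundant", "non_binder", "ambiguous",
                      "NUPs"))
  expect_error(assign_category(scores, thr, machinery = c(nup = "Oddball")),
               "unknown machinery")
})

test_that("category B relaxes exactly one A1 criterion by the configured factor", {
  base <- tibble::tibble(
    protein_id = "x",
    molar_fraction_bound = 1e-3,
    molar_fraction_input = 1e-5,
    input_enrichment = 5,
    ran_stimulation = 600,
    detected_in = "input,bait_minus_ran,bait_plus_ran"
  )
  relax <- thr$b$relax_factor
  # one criterion inside its relaxed band: B
  stim_b <- dplyr::mutate(base, ran_stimulation = 500 * relax + 1)
  expect_equal(assign_category(stim_b, thr), "B")
  enr_b <- dplyr::mutate(base, input_enrichment = 3 * relax + 0.01)
  expect_equal(assign_category(enr_b, thr), "B")
  mf_b <- dplyr::mutate(base, molar_fraction_bound = 1e-4 * relax * 1.01)
  expect_equal(assign_category(mf_b, thr), "B")
  # two relaxed criteria: not B
  two <- dplyr::mutate(base, ran_stimulation = 200, input_enrichment = 1.5)
  expect_equal(assign_category(two, thr), "ambiguous")
})

test_that("category assignment is monotone in stimulation and enrichment", {
  rank_of <- function(cat) {
    c(A1 = 3, A2 = 2, B = 1)[cat] |> (\(x) ifelse(is.na(x), 0, x))()
  }
  withr::with_seed(402, {
    scores <- random_scores(300)
    before <- rank_of(assign_category(scores, thr))
    for (col in c("ran_stimulation", "input_enrichment")) {
      bumped <- scores
      bumped[[col]] <- bumped[[col]] * 10
      after <- rank_of(assign_category(bumped, thr))
      expect_true(all(after >= before))
    }
  })
})

test_that("category assignment matches the brute-force oracle", {
  withr::with_seed(403, {
    for (i in 1:50) {
      scores <- random_scores(sample(1:50, 1))
      machinery <- NULL
      if (i %% 3 == 0) {
        picks <- sample(scores$protein_id, min(3, nrow(scores)))
        machinery <- stats::setNames(
          sample(c("NUPs", "NTRs", "NPC", "CRM1_cofactor"),
                 length(picks), replace = TRUE), picks)
      }
      got <- assign_category(scores, thr, machinery)
      want <- vapply(seq_len(nrow(scores)), function(j) {
        oracle_category(scores[j, ], thr, machinery)
      }, character(1))
      expect_equal(got, want)
    }
  })
})

test_that("a full experiment is scored coherently and a null experiment yields no A1", {
  p <- simulation_params(seed = 404, n_proteins = 400)
  truth <- generate_ground_truth(400, p)
  aff <- simulate_affinity_experiment(truth, p)
  res <- classify_experiment(aff, run_config())
  expect_equal(sum(res$census$n), nrow(res$scores))
  # per-sample fractions sum to one over detected proteins
  expect_equal(sum(res$scores$molar_fraction_bound, na.rm = TRUE), 1,
               tolerance = 1e-12)
  expect_equal(sum(res$scores$molar_fraction_input, na.rm = TRUE), 1,
               tolerance = 1e-12)
  # baseline-estimated scores are flagged
  est <- res$scores[which(res$scores$stimulation_is_bound_estimate), ]
  expect_true(all(grepl("bait_plus_ran", est$detected_in)))
  expect_true(all(!grepl("bait_minus_ran", est$detected_in)))

  null_truth <- dplyr::mutate(truth, cargo_strength = 0)
  null_res <- classify_experiment(simulate_affinity_experiment(null_truth, p),
                                  run_config())
  expect_equal(sum(null_res$scores$category == "A1"), 0)

  # a missing sample role is a configuration error
  expect_error(
    classify_experiment(dplyr::filter(aff, role != "input"), run_config()),
    "missing sample role"
  )
})
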