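test_that("RAS titration suite matches the reference assay layout", {
  truth <- default_truth("imidazole", "active")
  suite <- build_ras_titration_suite("active", truth, "imidazole")
  expect_s3_class(suite, "experiment_suite")
  expect_length(suite$designs, 6)
  ras <- vapply(suite$designs, `[[`, 0, "ras_total")
  expect_equal(ras, c(0, 1.25, 2.5, 5, 10, 20) * 1e-6)
  expect_true(all(vapply(suite$designs, `[[`, 0, "protease_total") == 1e-7))
  expect_true(all(vapply(suite$designs, `[[`, 0, "reporter_total") == 1e-6))
  expect_true(all(vapply(suite$designs, `[[`, 0, "r1_initial") == 0))
  # the RAS-free curve consumes at least half the reporter by the last time
  t_end <- max(suite$designs[[1]]$time_grid)
  endpoint <- oracle_closed_form(1e-6, truth$k_rep, 1e-7, t_end)
  expect_gte(endpoint, 0.5e-6)
})

test_that("r1 titration suite crosses the published grid", {
  truth <- default_truth("nitrite", "active")
  suite <- build_kp_titration_suite(truth, "nitrite")
  expect_length(suite$designs, 18)
  r1 <- vapply(suite$designs, `[[`, 0, "r1_initial")
  S0 <- vapply(suite$designs, `[[`, 0, "reporter_total")
  expect_equal(min(r1), 5e-8)      # exact published bounds
  expect_equal(max(r1), 3.3e-6)
  expect_setequal(unique(S0), c(0.1, 0.5, 1) * 1e-6)
  expect_true(all(vapply(suite$designs, `[[`, 0, "ras_total") == 0))
  expect_equal(nrow(unique(data.frame(r1, S0))), 18)  # full 6 x 3 cross
  expect_length(unique(r1), 6)
})

test_that("suite generation is deterministic and passes design validation", {
  truth <- default_truth("imidazole", "inactive")
  a <- build_ras_titration_suite("inactive", truth, "imidazole",
                                 noise = noise_model(0.01, 42))
  b <- build_ras_titration_suite("inactive", truth, "imidazole",
                                 noise = noise_model(0.01, 42))
  expect_identical(a, b)
  ca <- simulate_suite(a, noisy = TRUE, replicates = 2)
  cb <- simulate_suite(b, noisy = TRUE, replicates = 2)
  expect_identical(lapply(ca, `[[`, "amc"), lapply(cb, `[[`, "amc"))
  expect_length(ca, 12)
})

test_that("noise is additive, seeded, and of the requested magnitude", {
  kp <- quick_params()
  des <- quick_design(ras = 0, t_end = 3000, n = 1000)
  clean <- simulate_progress(des, kp)

  # sigma = 0 is the identity
  expect_identical(add_noise(clean, noise_model(0, 1)), clean)

  # same seed twice gives identical output; different seeds differ
  n1 <- add_noise(clean, noise_model(0.01, 7))
  n2 <- add_noise(clean, noise_model(0.01, 7))
  n3 <- add_noise(clean, noise_model(0.01, 8))
  expect_identical(n1$amc, n2$amc)
  expect_false(identical(n1$amc, n3$amc))
  expect_identical(n1$seed, 7L)

  # realized noise sd within 10% of sigma * reporter_total over 1000 points
  expect_equal(sd(n1$amc - clean$amc), 0.01 * des$reporter_total,
               tolerance = 0.1)

  # noisy curves cannot be re-noised
  expect_error(add_noise(n1, noise_model(0.01, 1)),
               class = "rascleave_usage_error")
})

test_that("add_noise leaves the caller's RNG stream untouched", {
  kp <- quick_params()
  clean <- simulate_progress(quick_design(ras = 0, n = 20), kp)
  set.seed(123)
  before <- .Random.seed
  invisible(add_noise(clean, noise_model(0.01, 5)))
  expect_identical(.Random.seed, before)
})

test_that("reporter concentration follows Beer-Lambert at 324 nm", {
  expect_equal(substrate_conc_from_absorbance(0, 1), 0)
  expect_equal(substrate_conc_from_absorbance(16, 1), 1e-3)   # 1 mM
  expect_equal(substrate_conc_from_absorbance(0.016, 1), 1e-6) # 1 uM
  expect_equal(substrate_conc_from_absorbance(0.016, 0.5), 2e-6)
  expect_error(substrate_conc_from_absorbance(-0.1, 1),
               class = "rascleave_domain_error")
})
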