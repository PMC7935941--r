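test_that("reporter specificity constant is recovered from a single curve", {
  kp <- quick_params(k_rep = 1e4)
  des <- quick_design(ras = 0, t_end = 4000, n = 200)
  clean <- simulate_progress(des, kp)
  est <- estimate_specificity_constant(clean)
  expect_equal(est$k, 1e4, tolerance = 1e-4)
  expect_true(est$se < 1e-2 * est$k)
})

test_that("flat curves raise a fit-failure condition, not a silent zero", {
  des <- quick_design(ras = 0, P0 = 0, n = 100)
  flat <- progress_curve(des$time_grid, rep(0, 100), des)
  expect_error(estimate_specificity_constant(flat),
               class = "rascleave_fit_error")
  # pure noise around zero also fails
  noisy <- progress_curve(des$time_grid,
                          with_seed_vec(1, 100, 1e-9), des,
                          noise_sigma = 1e-9, seed = 1)
  expect_error(estimate_specificity_constant(noisy),
               class = "rascleave_fit_error")
  # curves from designs containing RAS or r1 are rejected up front
  kp <- quick_params()
  cv <- simulate_progress(quick_design(ras = 5e-6, n = 30), kp)
  expect_error(estimate_specificity_constant(cv),
               class = "rascleave_usage_error")
})

test_that("single-curve estimate has calibrated uncertainty", {
  # Monte-Carlo coverage: truth within 3 SE in at least 95% of replicates
  kp <- quick_params(k_rep = 1e4)
  des <- quick_design(ras = 0, t_end = 4000, n = 200)
  clean <- simulate_progress(des, kp)
  hits <- vapply(1:100, function(s) {
    noisy <- add_noise(clean, noise_model(0.01, s))
    est <- estimate_specificity_constant(noisy)
    abs(est$k - 1e4) <= 3 * est$se
  }, TRUE)
  expect_gte(mean(hits), 0.95)
})

test_that("noiseless global fits recover the generator truth exactly", {
  truth <- quick_params()
  suite <- build_ras_titration_suite("active", truth, "imidazole",
                                     noise = noise_model(0),
                                     n_points = 80, t_mult = 6)
  curves <- simulate_suite(suite, noisy = FALSE)
  fit <- fit_global(suite, curves, fixed = list(K_P = truth$K_P),
                    n_starts = 5, n_polish = 1, seed = 3)
  for (nm in c("K_S", "k_2", "k_rep"))
    expect_equal(fit$estimates[[nm]], truth[[nm]], tolerance = 1e-3)
  expect_equal(fit$ratio, specificity_constant(truth), tolerance = 1e-3)
  # the derived ratio is exactly the ratio of the estimates
  expect_identical(fit$ratio, fit$estimates[["k_2"]] / fit$estimates[["K_S"]])
  # the best-so-far objective never increases across accepted iterations
  expect_true(all(diff(fit$rss_trace) <= 1e-12 * fit$rss_trace[1]))
})

test_that("the specificity ratio stays identifiable when K_S is not", {
  # with K_S far above the titration range, k_2 and K_S are individually
  # sloppy but their ratio is pinned by the initial-rate inhibition
  truth <- quick_params(K_S = 5e-5, k_2 = 5e-5 * 13720)
  suite <- build_ras_titration_suite("active", truth, "imidazole",
                                     noise = noise_model(0),
                                     n_points = 60, t_mult = 6)
  curves <- simulate_suite(suite, noisy = FALSE)
  fit <- fit_global(suite, curves, fixed = list(K_P = truth$K_P),
                    init = c(K_S = truth$K_S, k_2 = truth$k_2,
                             k_rep = truth$k_rep),
                    n_starts = 0, n_polish = 1)
  v <- fit$cov
  se_ratio <- sqrt(v["k_2", "k_2"] + v["K_S", "K_S"] - 2 * v["k_2", "K_S"])
  expect_lt(se_ratio, sqrt(v["k_2", "k_2"]))
  expect_lt(se_ratio, sqrt(v["K_S", "K_S"]))
})

test_that("profile likelihood brackets the estimate and collapses on noiseless data", {
  truth <- quick_params()
  suite <- build_ras_titration_suite("active", truth, "imidazole",
                                     noise = noise_model(0),
                                     n_points = 50, t_mult = 6)
  curves <- simulate_suite(suite, noisy = FALSE)
  fit <- fit_global(suite, curves, fixed = list(K_P = truth$K_P),
                    init = c(K_S = truth$K_S, k_2 = truth$k_2,
                             k_rep = truth$k_rep),
                    n_starts = 0, n_polish = 1)
  prof <- profile_specificity(fit, suite, curves, level = 0.95, n_grid = 6)
  expect_false(any(prof$unbounded))
  expect_lte(prof$lower, fit$ratio * (1 + 1e-9))
  expect_gte(prof$upper, fit$ratio * (1 - 1e-9))
  expect_lt((prof$upper - prof$lower) / fit$ratio, 0.005)
})

test_that("selectivity ratios reproduce the published folds", {
  expect_equal(selectivity_ratio(list(ratio = 1), list(ratio = 1)), 1)
  expect_equal(selectivity_ratio(list(ratio = 13720), list(ratio = 220)),
               62.4, tolerance = 0.005)   # printed as "60-fold"
  expect_equal(selectivity_ratio(list(ratio = 32430), list(ratio = 410)),
               79.1, tolerance = 0.005)   # printed as "80-fold"
  expect_error(selectivity_ratio(list(ratio = 1), list(ratio = 0)),
               class = "rascleave_domain_error")
  expect_error(selectivity_ratio(list(ratio = NaN), list(ratio = 1)),
               class = "rascleave_domain_error")
})

test_that("multi-start log records screened and polished starts", {
  truth <- quick_params()
  suite <- build_ras_titration_suite("active", truth, "imidazole",
                                     noise = noise_model(0),
                                     n_points = 30, t_mult = 4)
  curves <- simulate_suite(suite, noisy = FALSE)
  fit <- fit_global(suite, curves, fixed = list(K_P = truth$K_P),
                    n_starts = 6, n_polish = 2, seed = 11)
  expect_equal(nrow(fit$starts), 7)          # heuristic + 6 draws
  expect_equal(sum(fit$starts$polished), 2)
  expect_true(all(is.finite(fit$starts$rss_start)))
  expect_true(min(fit$starts$rss_final, na.rm = TRUE) <=
                min(fit$starts$rss_start))
})
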