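test_that("free protease partitioning solves the conservation equation", {
  # no ligands: all protease free
  expect_equal(free_protease(1e-7, 0, 0, 1e-6, 1e-6), 1e-7)
  # saturating excess of tight ligand drives free protease toward zero
  expect_lt(free_protease(1e-7, 2e-5, 0, 1e-9, 1e-6), 1e-9)
  # agreement with an independent bisection oracle to 10 significant digits
  cases <- list(c(1e-7, 1e-6, 1e-6, 1e-6, 1e-6),
                c(1e-7, 2e-5, 5e-6, 5e-6, 4e-7),
                c(1e-6, 1e-7, 3e-6, 1e-5, 1e-8),
                c(5e-8, 0, 3.3e-6, 1e-5, 4e-7))
  for (cs in cases) {
    got <- free_protease(cs[1], cs[2], cs[3], cs[4], cs[5])
    want <- oracle_free_p(cs[1], cs[2], cs[3], cs[4], cs[5])
    expect_equal(got, want, tolerance = 1e-10)
    # residual of the conservation equation itself
    resid <- got * (1 + cs[2] / (cs[4] + got) + cs[3] / (cs[5] + got)) - cs[1]
    expect_lt(abs(resid) / cs[1], 1e-10)
  }
  expect_error(free_protease(-1e-7, 0, 0, 1e-6, 1e-6),
               class = "rascleave_domain_error")
  expect_error(free_protease(1e-7, Inf, 0, 1e-6, 1e-6),
               class = "rascleave_domain_error")
  expect_error(free_protease(1e-7, 0, 0, 0, 1e-6),
               class = "rascleave_domain_error")
})

test_that("mechanism derivatives respect conservation and limiting cases", {
  kp <- quick_params()
  state <- c(R = 4e-6, P = 2e-8, RP = 5e-8, Pr1 = 3e-8, S = 8e-7,
             r1 = 9e-7, r2 = 1e-6, AMC = 2e-7)

  # zero protease: nothing moves
  d0 <- mechanism_rhs(state, kp, quick_design(ras = 4e-6, P0 = 0),
                      "rapid_equilibrium")
  expect_true(all(d0 == 0))
  dm <- mechanism_rhs(c(state, P = 0)[names(state)] * c(1, 0, 0, 0, 1, 1, 1, 1),
                      kp, quick_design(ras = 4e-6, P0 = 0), "mass_action")
  expect_true(all(dm == 0))

  # k_2 = 0 freezes the intact pool but the reporter is still consumed
  kp0 <- quick_params(k_2 = 1e-300)
  d <- mechanism_rhs(state, kp0, quick_design(ras = 4e-6), "rapid_equilibrium")
  expect_equal(unname(d[["R"]] + d[["RP"]]), 0, tolerance = 1e-290)
  expect_lt(d[["S"]], 0)

  # conservation groups sum to zero in both modes
  for (mode in c("rapid_equilibrium", "mass_action")) {
    d <- mechanism_rhs(state, kp, quick_design(ras = 4e-6), mode)
    expect_equal(unname(d[["P"]] + d[["RP"]] + d[["Pr1"]]), 0)
    expect_equal(unname(d[["R"]] + d[["RP"]] + d[["r1"]] + d[["Pr1"]]), 0)
    expect_equal(unname(d[["S"]] + d[["AMC"]]), 0)
  }

  expect_error(mechanism_rhs(state, kp, quick_design(), "nonsense"),
               class = "rascleave_usage_error")
})

test_that("reported derivatives match finite differences of the simulation", {
  kp <- quick_params()
  des <- quick_design(ras = 5e-6, t_end = 2000, n = 201)
  cv <- simulate_progress(des, kp)
  tr <- attr(cv, "trajectory")
  dt <- diff(des$time_grid)[1]
  for (i in c(51, 101, 151)) {
    st <- unlist(tr[i, c("R", "P", "RP", "Pr1", "S", "r1", "r2", "AMC")])
    d <- mechanism_rhs(st, kp, des, "rapid_equilibrium")
    # centered differences of the conserved pools
    d_amc <- (tr$AMC[i + 1] - tr$AMC[i - 1]) / (2 * dt)
    d_r2 <- (tr$r2[i + 1] - tr$r2[i - 1]) / (2 * dt)
    expect_equal(unname(d[["AMC"]]), d_amc, tolerance = 1e-4)
    expect_equal(unname(d[["r2"]]), d_r2, tolerance = 1e-4)
  }
})

test_that("RAS-free simulation reproduces the closed-form exponential", {
  kp <- quick_params()
  des <- quick_design(ras = 0, t_end = 2500, n = 101)
  cv <- simulate_progress(des, kp)
  want <- oracle_closed_form(des$reporter_total, kp$k_rep,
                             des$protease_total, des$time_grid)
  expect_equal(cv$amc[1], 0)
  rel <- abs(cv$amc - want) / pmax(want, 1e-15)
  expect_lt(max(rel), 1e-6)
})

test_that("simulated curves start at zero, stay monotone, and conserve mass", {
  kp <- quick_params()
  for (des in list(quick_design(ras = 0), quick_design(ras = 2e-5),
                   quick_design(ras = 1e-6, r1 = 2e-6))) {
    cv <- simulate_progress(des, kp)
    expect_equal(cv$amc[1], 0)
    expect_equal(attr(cv, "trajectory")$S[1], des$reporter_total)
    expect_true(all(diff(cv$amc) >= 0))
    expect_lt(max(conservation_drift(cv)), 1e-6)
  }
})

test_that("compiled and pure-R right-hand sides give the same trajectories", {
  kp <- quick_params()
  des <- quick_design(ras = 5e-6, r1 = 5e-7, n = 31)
  for (mode in c("rapid_equilibrium", "mass_action")) {
    a <- simulate_progress(des, kp, mode = mode, compiled = TRUE)
    b <- simulate_progress(des, kp, mode = mode, compiled = FALSE)
    expect_equal(a$amc, b$amc, tolerance = 1e-8)
  }
})

test_that("mass action converges to the rapid-equilibrium reduction", {
  kp <- quick_params()
  des <- quick_design(ras = 5e-6, t_end = 4000, n = 51)
  re <- simulate_progress(des, kp)$amc
  disc <- vapply(c(1e7, 1e8, 1e9), function(kon) {
    p <- kinetic_params(kp$K_S, kp$k_2, kp$K_P, kp$k_rep, k_on = kon)
    max(abs(simulate_progress(des, p, mode = "mass_action")$amc - re))
  }, 0) / des$reporter_total
  expect_true(all(diff(disc) < 0))      # discrepancy shrinks with kon
  expect_lt(disc[3], 0.005)             # within 0.5% of reporter at 1e9
})

test_that("AMC at fixed time is nonincreasing in RAS and in r1", {
  kp <- quick_params()
  ras_grid <- c(0, 1.25, 2.5, 5, 10, 20) * 1e-6
  ends <- vapply(ras_grid, function(r) {
    cv <- simulate_progress(quick_design(ras = r, n = 21), kp)
    cv$amc[21]
  }, 0)
  expect_true(all(diff(ends) < 0))
  r1_grid <- c(0, 5e-8, 5e-7, 3.3e-6)
  ends <- vapply(r1_grid, function(r1) {
    simulate_progress(quick_design(ras = 0, r1 = r1, n = 21), kp)$amc[21]
  }, 0)
  expect_true(all(diff(ends) < 0))
})

test_that("a larger specificity constant cleaves RAS faster at every time", {
  fast <- quick_params(k_2 = 0.0686)            # k2/KS = 13720
  slow <- quick_params(k_2 = 0.0686 / 60)       # same KS, 60-fold lower ratio
  des <- quick_design(ras = 5e-6, n = 41)
  cf <- attr(simulate_progress(des, fast), "trajectory")$r2
  cs <- attr(simulate_progress(des, slow), "trajectory")$r2
  expect_true(all(cf[-1] > cs[-1]))
})

test_that("trajectory export writes one row per time with all species", {
  kp <- quick_params()
  cv <- simulate_progress(quick_design(n = 11), kp)
  path <- withr::local_tempfile(fileext = ".csv")
  write_trajectory(cv, path)
  tab <- read.csv(path)
  expect_identical(names(tab),
                   c("curve_id", "time_s", "R", "P", "RP", "Pr1", "S", "r1",
                     "r2", "AMC"))
  expect_equal(nrow(tab), 11)
  expect_equal(tab$AMC, cv$amc, tolerance = 1e-12)
})
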