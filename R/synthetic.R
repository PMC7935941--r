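#' Additive Gaussian noise model
#'
#' Homoscedastic additive noise on the AMC signal, with standard deviation
#' expressed as a fraction of the design's reporter concentration (default 1%,
#' typical of stopped-flow / plate-reader fluorescence after calibration).
#'
#' @param sigma Noise standard deviation as a fraction of `reporter_total`.
#' @param seed Integer seed for reproducible draws.
#' @return An object of class `noise_model`.
#' @export
noise_model <- function(sigma = 0.01, seed = 1L) {
  if (!is.numeric(sigma) || length(sigma) != 1L || !is.finite(sigma) ||
      sigma < 0)
    stop_domain("'sigma' must be a single finite non-negative number")
  structure(list(sigma = sigma, seed = as.integer(seed)),
            class = "noise_model")
}

#' Generator-truth kinetic parameters for the two RAS proteases
#'
#' Default parameter sets for the imidazole-dependent and nitrite-dependent
#' RAS-specific proteases acting on active (GMPPNP-loaded) and inactive
#' (GDP-loaded) RAS.  The specificity constants k_2/K_S are the published
#' values for these enzymes (13,720 and 220 M^-1 s^-1 for the
#' imidazole-dependent protease, 32,430 and 410 M^-1 s^-1 for the
#' nitrite-dependent one).  The split of the ratio into K_S and k_2, the
#' product dissociation constant K_P and the reporter specificity constant
#' are not published individually and are package defaults: K_S = 5 uM for
#' active RAS and 20 uM for the weaker-binding inactive form, K_P = 0.4 uM
#' (the logarithmic midpoint of the 50 nM - 3.3 uM product titration), and
#' k_rep = 2e4 (imidazole) or 3e4 (nitrite) M^-1 s^-1 in 1 mM cofactor.
#'
#' @param protease `"imidazole"` or `"nitrite"` (the cofactor that activates
#'   the enzyme).
#' @param ras_form `"active"` or `"inactive"`.
#' @return A [kinetic_params()] object.
#' @examples
#' specificity_constant(default_truth("imidazole", "active"))
#' @export
default_truth <- function(protease = c("imidazole", "nitrite"),
                          ras_form = c("active", "inactive")) {
  protease <- match.arg(protease)
  ras_form <- match.arg(ras_form)
  ratio <- switch(protease,
                  imidazole = c(active = 13720, inactive = 220),
                  nitrite = c(active = 32430, inactive = 410))[[ras_form]]
  K_S <- switch(ras_form, active = 5e-6, inactive = 2e-5)
  k_rep <- switch(protease, imidazole = 2e4, nitrite = 3e4)
  kinetic_params(K_S = K_S, k_2 = ratio * K_S, K_P = 4e-7, k_rep = k_rep)
}

#' Suite of assay designs sharing one enzyme and one truth
#'
#' @param label Suite label.
#' @param designs List of [assay_design()] objects.
#' @param truth Generator-truth [kinetic_params()].
#' @param noise A [noise_model()].
#' @return An object of class `experiment_suite`.
#' @export
experiment_suite <- function(label, designs, truth, noise = noise_model()) {
  stopifnot(is.character(label), length(label) == 1L,
            inherits(truth, "kinetic_params"), inherits(noise, "noise_model"))
  if (!length(designs) || !all(vapply(designs, inherits, TRUE, "assay_design")))
    stop_domain("'designs' must be a non-empty list of assay_design objects")
  pt <- vapply(designs, `[[`, 0, "protease_total")
  cf <- vapply(designs, `[[`, "", "cofactor_id")
  if (length(unique(pt)) != 1L || length(unique(cf)) != 1L)
    stop_domain("all designs in a suite must share protease_total and cofactor")
  structure(list(label = label, designs = designs, truth = truth,
                 noise = noise), class = "experiment_suite")
}

#' @export
print.experiment_suite <- function(x, ...) {
  cat(sprintf("Experiment suite '%s': %d designs, noise %.3g%%\n", x$label,
              length(x$designs), 100 * x$noise$sigma))
  invisible(x)
}

#' RAS titration suite
#'
#' Builds the six-curve RAS titration of the reference assay: 100 nM protease
#' and 1 uM QEEYSAM-AMC reporter, with RAS varied over 0, 1.25, 2.5, 5, 10
#' and 20 uM (a doubling grid across the published 0-20 uM range, chosen for
#' identifiability of K_S).  The shared time grid is auto-scaled from the
#' truth parameters: `n_points` samples over `t_mult` reporter time constants
#' `1 / (k_rep * protease_total)`, so the RAS-free curve consumes well over
#' half of the reporter and the later points carry the product-inhibition
#' signature.
#'
#' @param ras_form `"active"` or `"inactive"`.
#' @param truth Generator-truth [kinetic_params()].
#' @param cofactor_id `"imidazole"` or `"nitrite"`.
#' @param cofactor_conc Cofactor concentration (M), default 1 mM.
#' @param noise A [noise_model()].
#' @param n_points Samples per curve (default 200).
#' @param t_mult Observation window in reporter time constants (default 8).
#' @return An [experiment_suite()] of six designs.
#' @export
build_ras_titration_suite <- function(ras_form = c("active", "inactive"),
                                      truth,
                                      cofactor_id = c("imidazole", "nitrite"),
                                      cofactor_conc = 1e-3,
                                      noise = noise_model(),
                                      n_points = 200, t_mult = 8) {
  ras_form <- match.arg(ras_form)
  cofactor_id <- match.arg(cofactor_id)
  stopifnot(inherits(truth, "kinetic_params"))
  protease_total <- 1e-7
  reporter_total <- 1e-6
  tau <- 1 / (truth$k_rep * protease_total)
  times <- seq(0, t_mult * tau, length.out = n_points)
  ras <- c(0, 1.25, 2.5, 5, 10, 20) * 1e-6
  designs <- lapply(ras, function(r)
    assay_design(protease_total, r, if (r > 0) ras_form else "none",
                 reporter_total, 0, cofactor_id, cofactor_conc, times))
  experiment_suite(sprintf("ras_titration_%s_%s", cofactor_id, ras_form),
                   designs, truth, noise)
}

#' Product-fragment (r1) titration suite
#'
#' Builds the product-inhibition titration used to determine K_P
#' independently of RAS cleavage: no RAS, purified r1 fragment on a six-point
#' logarithmic grid from 50 nM to 3.3 uM, crossed with reporter at 0.1, 0.5
#' and 1 uM (18 designs).  With no intact RAS present the free protease is
#' constant in time and each curve is a single exponential whose rate encodes
#' the r1 occupancy.
#'
#' @inheritParams build_ras_titration_suite
#' @param n_points Samples per curve (default 100).
#' @param t_mult Observation window in reporter time constants (default 4).
#' @return An [experiment_suite()] of 18 designs.
#' @export
build_kp_titration_suite <- function(truth,
                                     cofactor_id = c("imidazole", "nitrite"),
                                     cofactor_conc = 1e-3,
                                     noise = noise_model(),
                                     n_points = 100, t_mult = 4) {
  cofactor_id <- match.arg(cofactor_id)
  stopifnot(inherits(truth, "kinetic_params"))
  protease_total <- 1e-7
  tau <- 1 / (truth$k_rep * protease_total)
  times <- seq(0, t_mult * tau, length.out = n_points)
  r1 <- exp(seq(log(5e-8), log(3.3e-6), length.out = 6))
  r1[1] <- 5e-8; r1[6] <- 3.3e-6  # exact published bounds
  grid <- expand.grid(r1 = r1, S0 = c(0.1, 0.5, 1) * 1e-6)
  designs <- lapply(seq_len(nrow(grid)), function(i)
    assay_design(protease_total, 0, "none", grid$S0[i], grid$r1[i],
                 cofactor_id, cofactor_conc, times))
  experiment_suite(sprintf("kp_titration_%s", cofactor_id), designs, truth,
                   noise)
}

#' Add measurement noise to a progress curve
#'
#' Adds i.i.d. Gaussian noise with standard deviation
#' `sigma * reporter_total` to a noiseless curve.  The draw is seeded and
#' reproducible; the caller's RNG state is left untouched.
#'
#' @param curve A noiseless [progress_curve()].
#' @param model A [noise_model()].
#' @return A [progress_curve()] with recorded `noise_sigma` and `seed`.
#' @export
add_noise <- function(curve, model) {
  stopifnot(inherits(curve, "progress_curve"), inherits(model, "noise_model"))
  if (curve$noise_sigma > 0)
    stop_usage("add_noise() expects a noiseless curve")
  if (model$sigma == 0) return(curve)
  sd_abs <- model$sigma * curve$design$reporter_total
  noisy <- curve$amc + with_local_seed(model$seed,
                                       stats::rnorm(length(curve$amc), 0, sd_abs))
  out <- curve
  out$amc <- noisy
  out$noise_sigma <- sd_abs
  out$seed <- model$seed
  out
}

# run code under a fixed seed without disturbing the caller's RNG stream
with_local_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Simulate all curves of a suite
#'
#' Simulates every design of a suite under the suite's truth parameters and,
#' optionally, adds seeded replicate noise.  Replicate `k` of design `i`
#' draws its noise with seed `noise$seed + 1000 * i + k`, so the whole
#' suite is reproducible from the suite definition alone.
#'
#' @param suite An [experiment_suite()].
#' @param noisy Add noise? Default `TRUE`.
#' @param replicates Noisy replicates per design (default 1).
#' @param mode Simulation mode passed to [simulate_progress()].
#' @return A list of [progress_curve()] objects, each carrying a
#'   `design_index` attribute mapping it to `suite$designs`.
#' @export
simulate_suite <- function(suite, noisy = TRUE, replicates = 1,
                           mode = "rapid_equilibrium") {
  stopifnot(inherits(suite, "experiment_suite"))
  out <- list()
  for (i in seq_along(suite$designs)) {
    clean <- simulate_progress(suite$designs[[i]], suite$truth, mode = mode)
    if (!noisy || suite$noise$sigma == 0) {
      clean$curve_id <- sprintf("%s_d%02d", suite$label, i)
      attr(clean, "design_index") <- i
      out[[length(out) + 1L]] <- clean
      next
    }
    for (k in seq_len(replicates)) {
      nm <- noise_model(suite$noise$sigma,
                        suite$noise$seed + 1000L * i + k)
      noisy_cv <- add_noise(clean, nm)
      noisy_cv$curve_id <- sprintf("%s_d%02d_r%d", suite$label, i, k)
      attr(noisy_cv, "design_index") <- i
      out[[length(out) + 1L]] <- noisy_cv
    }
  }
  out
}

#' Reporter concentration from absorbance at 324 nm
#'
#' Converts an A324 reading to the molar concentration of the AMC reporter
#' peptide using the extinction coefficient 16 mM^-1 cm^-1.
#'
#' @param A324 Absorbance at 324 nm.
#' @param pathlength Cuvette path length (cm), default 1.
#' @return Concentration (M).
#' @examples
#' substrate_conc_from_absorbance(0.016) # 1 uM
#' @export
substrate_conc_from_absorbance <- function(A324, pathlength = 1) {
  if (!is.numeric(A324) || any(!is.finite(A324)) || any(A324 < 0))
    stop_domain("'A324' must be finite and non-negative")
  if (!is.numeric(pathlength) || any(pathlength <= 0))
    stop_domain("'pathlength' must be positive")
  A324 / (16e3 * pathlength)
}
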