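#' Kinetic parameters of the RAS-cleavage mechanism
#'
#' Bundles the constants of the minimal cleavage mechanism: reversible binding
#' of intact RAS to the protease (dissociation constant `K_S`), irreversible
#' acylation of the bound complex at rate `k_2` (releasing the C-terminal
#' fragment r2 and leaving the N-terminal fragment r1 bound), and reversible
#' rebinding of the r1 product (dissociation constant `K_P`).  The fluorogenic
#' reporter peptide (QEEYSAM-AMC) is consumed far below saturation, so its
#' turnover is governed by a single specificity constant `k_rep` (kcat/KM)
#' acting on free protease.  `k_on` is used only when the equilibria are
#' expanded into mass action (off-rates are `k_on * K`).
#'
#' @param K_S Dissociation constant of the protease-RAS complex (M).
#' @param k_2 Acylation rate constant, the first chemical step of cleavage
#'   (s^-1).
#' @param K_P Dissociation constant of the protease-r1 product complex (M).
#' @param k_rep Reporter specificity constant kcat/KM for QEEYSAM-AMC
#'   (M^-1 s^-1).
#' @param k_on Association rate constant used to expand the equilibria into
#'   mass action (M^-1 s^-1).  Default 1e7.
#'
#' @return An object of class `kinetic_params`: a named list with the five
#'   constants and the derived specificity constant accessible via
#'   [specificity_constant()].
#' @examples
#' kp <- kinetic_params(K_S = 5e-6, k_2 = 0.0686, K_P = 4e-7, k_rep = 2e4)
#' specificity_constant(kp)
#' @export
kinetic_params <- function(K_S, k_2, K_P, k_rep, k_on = 1e7) {
  p <- list(K_S = K_S, k_2 = k_2, K_P = K_P, k_rep = k_rep, k_on = k_on)
  for (nm in names(p)) {
    v <- p[[nm]]
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v) || v <= 0)
      stop_domain(sprintf("'%s' must be a single finite positive number", nm))
  }
  structure(p, class = "kinetic_params")
}

#' Derived specificity constant k_2/K_S
#'
#' @param params A [kinetic_params()] object.
#' @return The second-order rate constant for RAS cleavage at sub-saturating
#'   RAS, `k_2 / K_S` (M^-1 s^-1).
#' @export
specificity_constant <- function(params) {
  stopifnot(inherits(params, "kinetic_params"))
  params$k_2 / params$K_S
}

#' @export
print.kinetic_params <- function(x, ...) {
  cat("Kinetic parameters (RAS-cleavage mechanism)\n")
  cat(sprintf("  K_S   = %.4g M\n", x$K_S))
  cat(sprintf("  k_2   = %.4g s^-1\n", x$k_2))
  cat(sprintf("  K_P   = %.4g M\n", x$K_P))
  cat(sprintf("  k_rep = %.4g M^-1 s^-1\n", x$k_rep))
  cat(sprintf("  k_on  = %.4g M^-1 s^-1 (mass-action expansion only)\n", x$k_on))
  cat(sprintf("  k_2/K_S = %.4g M^-1 s^-1\n", x$k_2 / x$K_S))
  invisible(x)
}

#' Assay design for one progress curve
#'
#' Describes the initial conditions and observation grid of a single
#' fluorogenic progress-curve assay: protease, RAS (in either nucleotide
#' state), reporter peptide, optionally pre-added r1 product fragment, and the
#' cofactor context (which selects the parameter values; the cofactor does not
#' enter the rate equations).
#'
#' @param protease_total Total protease concentration (M).
#' @param ras_total Total intact RAS at t = 0 (M).
#' @param ras_form `"active"` (GMPPNP/GTP-loaded) or `"inactive"` (GDP) or
#'   `"none"`.
#' @param reporter_total Total reporter peptide at t = 0 (M).
#' @param r1_initial Pre-added r1 fragment (M); used in product-inhibition
#'   titrations.
#' @param cofactor_id `"imidazole"`, `"nitrite"` or `"none"`.
#' @param cofactor_conc Cofactor concentration (M).
#' @param time_grid Strictly increasing observation times starting at 0 (s).
#'
#' @return An object of class `assay_design`.
#' @examples
#' assay_design(1e-7, 5e-6, "active", 1e-6, 0, "imidazole", 1e-3,
#'              seq(0, 1000, by = 10))
#' @export
assay_design <- function(protease_total, ras_total = 0,
                         ras_form = c("none", "active", "inactive"),
                         reporter_total = 1e-6, r1_initial = 0,
                         cofactor_id = c("none", "imidazole", "nitrite"),
                         cofactor_conc = 0, time_grid) {
  ras_form <- match.arg(ras_form)
  cofactor_id <- match.arg(cofactor_id)
  conc <- c(protease_total = protease_total, ras_total = ras_total,
            reporter_total = reporter_total, r1_initial = r1_initial,
            cofactor_conc = cofactor_conc)
  for (nm in names(conc)) {
    v <- conc[[nm]]
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v) || v < 0)
      stop_domain(sprintf("'%s' must be a single finite non-negative number", nm))
  }
  if (!is.numeric(time_grid) || length(time_grid) < 2L ||
      any(!is.finite(time_grid)))
    stop_domain("'time_grid' must be a finite numeric vector of length >= 2")
  if (time_grid[1] != 0)
    stop_domain("'time_grid' must start at 0")
  if (any(diff(time_grid) <= 0))
    stop_domain("'time_grid' must be strictly increasing")
  structure(list(protease_total = protease_total, ras_total = ras_total,
                 ras_form = ras_form, reporter_total = reporter_total,
                 r1_initial = r1_initial, cofactor_id = cofactor_id,
                 cofactor_conc = cofactor_conc, time_grid = time_grid),
            class = "assay_design")
}

#' @export
print.assay_design <- function(x, ...) {
  cat(sprintf(
    "Assay design: %.3g nM protease, %.3g uM RAS (%s), %.3g uM reporter,\n",
    x$protease_total * 1e9, x$ras_total * 1e6, x$ras_form,
    x$reporter_total * 1e6))
  cat(sprintf("  %.3g uM r1, cofactor %s (%.3g mM), %d times over %.3g s\n",
              x$r1_initial * 1e6, x$cofactor_id, x$cofactor_conc * 1e3,
              length(x$time_grid), max(x$time_grid)))
  invisible(x)
}

#' Progress curve container
#'
#' Time series of released AMC (molar product concentration) for one assay
#' design, with noise provenance.  Noiseless curves are monotone
#' nondecreasing; noisy curves record the noise standard deviation and seed
#' used.
#'
#' @param time Observation times (s).
#' @param amc Released AMC (M).
#' @param design The [assay_design()] the curve belongs to.
#' @param noise_sigma Additive Gaussian noise standard deviation (M); 0 for a
#'   noiseless model curve.
#' @param seed Integer seed used to draw the noise, or `NA` for noiseless.
#' @param curve_id Optional identifier.
#'
#' @return An object of class `progress_curve`.
#' @export
progress_curve <- function(time, amc, design, noise_sigma = 0, seed = NA,
                           curve_id = NA_character_) {
  stopifnot(inherits(design, "assay_design"))
  if (length(time) != length(amc))
    stop_domain("'time' and 'amc' must have equal length")
  band <- 5 * max(noise_sigma, 0)
  if (any(amc < -band - 1e-12) || any(amc > design$reporter_total + band + 1e-12))
    stop_domain("'amc' outside the physical range of the design")
  structure(list(time = time, amc = amc, design = design,
                 noise_sigma = noise_sigma, seed = seed, curve_id = curve_id),
            class = "progress_curve")
}

#' @export
print.progress_curve <- function(x, ...) {
  cat(sprintf("Progress curve '%s': %d points over %.3g s, endpoint %.3g uM AMC",
              x$curve_id, length(x$time), max(x$time),
              x$amc[length(x$amc)] * 1e6))
  if (x$noise_sigma > 0)
    cat(sprintf(" (noise sd %.3g M, seed %s)", x$noise_sigma,
                format(x$seed)))
  cat("\n")
  invisible(x)
}

# internal condition helpers --------------------------------------------------

stop_domain <- function(msg) {
  stop(errorCondition(msg, class = c("rascleave_domain_error", "rascleave_error")))
}

stop_usage <- function(msg) {
  stop(errorCondition(msg, class = c("rascleave_usage_error", "rascleave_error")))
}

stop_numerical <- function(msg, diagnostics = NULL) {
  stop(errorCondition(msg, diagnostics = diagnostics,
                      class = c("rascleave_numerical_error", "rascleave_error")))
}

stop_fit <- function(msg, diagnostics = NULL) {
  stop(errorCondition(msg, diagnostics = diagnostics,
                      class = c("rascleave_fit_error", "rascleave_error")))
}
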