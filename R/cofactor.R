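#' Cofactor activation parameters
#'
#' Parameters of the saturable activation of an active-site-deleted protease
#' by its rescuing cofactor (imidazole for H64G variants, nitrite for D32G
#' variants).  The observable is the specificity constant kcat/KM for the
#' reporter substrate as a function of cofactor concentration; the default
#' functional form is a hyperbola (Hill exponent `h = 1`), with `h` exposed
#' because the underlying binding need not be strictly 1:1.
#'
#' @param v0 Basal specificity constant at zero cofactor (M^-1 s^-1).
#' @param v_max Saturating specificity constant (M^-1 s^-1).
#' @param K_act Cofactor half-activation concentration (M).
#' @param h Cooperativity exponent, default 1.
#' @return An object of class `activation_params`.
#' @export
activation_params <- function(v0, v_max, K_act, h = 1) {
  if (!is.numeric(v0) || v0 < 0 || !is.finite(v0))
    stop_domain("'v0' must be finite and non-negative")
  if (!is.numeric(v_max) || !is.finite(v_max) || v_max < v0)
    stop_domain("'v_max' must be finite and >= v0")
  if (!is.numeric(K_act) || !is.finite(K_act) || K_act <= 0)
    stop_domain("'K_act' must be finite and positive")
  if (!is.numeric(h) || !is.finite(h) || h <= 0)
    stop_domain("'h' must be finite and positive")
  structure(list(v0 = v0, v_max = v_max, K_act = K_act, h = h),
            class = "activation_params")
}

#' Activity at a given cofactor concentration
#'
#' Evaluates the saturation curve
#' \deqn{v(c) = v_0 + (v_{max} - v_0)\,\frac{c^h}{K_{act}^h + c^h}.}
#'
#' @param c Cofactor concentration (M); may be a vector.
#' @param p An [activation_params()] object.
#' @return Specificity constant(s) (M^-1 s^-1); continuous, nondecreasing in
#'   `c` and bounded by `[v0, v_max]`.
#' @export
activation_value <- function(c, p) {
  stopifnot(inherits(p, "activation_params"))
  if (!is.numeric(c) || any(!is.finite(c)) || any(c < 0))
    stop_domain("cofactor concentration must be finite and non-negative")
  ch <- c^p$h
  p$v0 + (p$v_max - p$v0) * ch / (p$K_act^p$h + ch)
}

#' Fit an activation curve
#'
#' Least-squares fit of [activation_value()] to measured
#' (cofactor concentration, specificity constant) points.  The Hill exponent
#' is held at `h` (default 1) unless `fit_h = TRUE`.  Degenerate designs are
#' flagged rather than silently fitted: a curve that is flat relative to its
#' residual scatter, or whose half-activation constant is not bracketed by
#' the data, sets `k_act_identifiable = FALSE` in the result.
#'
#' @param points Data frame (or matrix) with columns `cofactor_M` and
#'   `specificity_constant`, at least 4 rows.
#' @param h Fixed Hill exponent (ignored when `fit_h = TRUE`).
#' @param fit_h Also estimate the exponent? Default `FALSE`.
#' @return An object of class `activation_fit`: `params`
#'   ([activation_params()]), `se` (named), `k_act_identifiable`, `rss`, and
#'   the underlying `nls` fit.
#' @export
fit_activation <- function(points, h = 1, fit_h = FALSE) {
  points <- as.data.frame(points)
  if (!all(c("cofactor_M", "specificity_constant") %in% names(points)))
    stop_usage("'points' needs columns cofactor_M and specificity_constant")
  if (nrow(points) < 4)
    stop_usage("at least 4 points are required")
  cc <- points$cofactor_M
  vv <- points$specificity_constant
  if (any(!is.finite(cc)) || any(cc < 0) || any(!is.finite(vv)))
    stop_domain("non-finite or negative inputs in 'points'")

  v0s <- max(min(vv), 0)
  vms <- max(vv)
  Ks <- exp(mean(log(cc[cc > 0])))
  df <- data.frame(c = cc, v = vv)
  span <- vms - v0s

  fit <- tryCatch({
    if (fit_h)
      minpack.lm::nlsLM(v ~ v0 + (vmax - v0) * c^h / (K^h + c^h), data = df,
                        start = list(v0 = v0s, vmax = vms, K = Ks, h = h),
                        lower = c(0, 0, 1e-12, 0.1),
                        control = minpack.lm::nls.lm.control(maxiter = 300))
    else
      minpack.lm::nlsLM(v ~ v0 + (vmax - v0) * c^h / (K^h + c^h), data = df,
                        start = list(v0 = v0s, vmax = vms, K = Ks),
                        lower = c(0, 0, 1e-12),
                        control = minpack.lm::nls.lm.control(maxiter = 300))
  }, error = function(e) stop_fit(paste("activation fit failed:",
                                        conditionMessage(e))))
  sm <- summary(fit)
  co <- sm$coefficients
  est <- co[, "Estimate"]
  se <- co[, "Std. Error"]
  hhat <- if (fit_h) est[["h"]] else h

  resid_sd <- stats::sd(stats::residuals(fit))
  flat <- (est[["vmax"]] - est[["v0"]]) < 4 * resid_sd
  outside <- est[["K"]] < min(cc[cc > 0]) / 2 || est[["K"]] > max(cc) * 2
  wide <- is.finite(se[["K"]]) && se[["K"]] > est[["K"]]
  identifiable <- !(flat || outside || wide)
  if (!identifiable)
    warning("K_act is not identifiable from these points (flat or one-sided design)",
            call. = FALSE)

  structure(list(params = activation_params(max(est[["v0"]], 0),
                                            max(est[["vmax"]], est[["v0"]], 0),
                                            est[["K"]], hhat),
                 se = se, k_act_identifiable = identifiable,
                 rss = sum(stats::residuals(fit)^2), fit = fit),
            class = "activation_fit")
}

#' @export
print.activation_fit <- function(x, ...) {
  p <- x$params
  cat(sprintf("Activation fit: v0 = %.4g, v_max = %.4g M^-1 s^-1, K_act = %.4g M (h = %.3g)\n",
              p$v0, p$v_max, p$K_act, p$h))
  if (!x$k_act_identifiable) cat("  [K_act not identifiable]\n")
  invisible(x)
}

#' Cognate / non-cognate activity fold at a cofactor concentration
#'
#' Ratio of the activation curves of a cognate substrate (P4 = Tyr) and a
#' near-cognate one (P4 = Ile) at cofactor concentration `c`; the currency of
#' the substrate-cofactor linkage (of order 100-fold in 1 mM nitrite and
#' 300-fold in 1 mM imidazole for the engineered RAS proteases).
#'
#' @param p_cognate,p_noncognate [activation_params()] for the two substrates.
#' @param c Cofactor concentration (M); may be a vector.
#' @return Dimensionless fold (vector over `c`).
#' @export
cognate_fold <- function(p_cognate, p_noncognate, c) {
  num <- activation_value(c, p_cognate)
  den <- activation_value(c, p_noncognate)
  if (any(den == 0))
    stop_domain("non-cognate activity is zero; fold undefined")
  num / den
}

#' Two-state conformational linkage
#'
#' Formalises the verbal two-state picture of cofactor rescue: the enzyme
#' equilibrates between an inactive and an activatable conformation
#' (equilibrium constant `L` = inactive/active), cofactor binding (dissociation
#' constant `K_act_active` for the active state) and cognate sub-site
#' stabilisation (Boltzmann factor `delta_g_substrate`) both pull the
#' equilibrium toward the active form.  The activatable fraction is
#' \deqn{f = \frac{(1 + c/K)\,\delta}{L + (1 + c/K)\,\delta}.}
#' This is an illustrative formalisation of the conformational-selection
#' argument, not a model fitted to data.
#'
#' @param L Inactive/active conformational equilibrium constant (> 0).
#' @param K_act_active Cofactor dissociation constant for the active state (M).
#' @param delta_g_substrate Boltzmann factor for cognate sub-site
#'   stabilisation (> 0; 1 = no stabilisation).
#' @param c Cofactor concentration (M); may be a vector.
#' @return Fraction of enzyme in the activatable state, in (0, 1);
#'   monotonically increasing in both `c` and `delta_g_substrate`.
#' @examples
#' two_state_linkage(L = 9, K_act_active = 1e-4, delta_g_substrate = 1, c = 0)
#' @export
two_state_linkage <- function(L, K_act_active, delta_g_substrate, c) {
  if (!is.numeric(L) || L <= 0 || !is.finite(L))
    stop_domain("'L' must be finite and positive")
  if (!is.numeric(K_act_active) || K_act_active <= 0 ||
      !is.finite(K_act_active))
    stop_domain("'K_act_active' must be finite and positive")
  if (!is.numeric(delta_g_substrate) || delta_g_substrate <= 0 ||
      !is.finite(delta_g_substrate))
    stop_domain("'delta_g_substrate' must be finite and positive")
  if (!is.numeric(c) || any(!is.finite(c)) || any(c < 0))
    stop_domain("cofactor concentration must be finite and non-negative")
  a <- (1 + c / K_act_active) * delta_g_substrate
  a / (L + a)
}
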