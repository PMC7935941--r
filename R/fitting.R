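#' Estimate the reporter specificity constant from a single curve
#'
#' In the absence of RAS and r1 the free protease is constant, so the
#' reporter progress curve is the single exponential
#' \deqn{AMC(t) = S_0 (1 - e^{-k\,P_{tot}\,t}) + b}
#' with `k` the specificity constant kcat/KM (the first-order regime: the
#' 1 uM reporter is far below saturation).  The constant is estimated by
#' nonlinear least squares with an optional baseline `b`.
#'
#' @param curve A [progress_curve()] from a RAS-free, r1-free design.
#' @param protease_total Total protease (M); default from the design.
#' @param reporter_total Total reporter (M); default from the design.
#' @param baseline Also fit an additive baseline? Default `FALSE`.
#' @return An object of class `specificity_fit`: list with `k` (M^-1 s^-1),
#'   `se`, optional `baseline`, and the underlying `nls` fit.
#'   A flat or non-monotone curve beyond noise raises a fit-failure
#'   condition (class `rascleave_fit_error`), never a silent zero.
#' @export
estimate_specificity_constant <- function(curve, protease_total = NULL,
                                          reporter_total = NULL,
                                          baseline = FALSE) {
  stopifnot(inherits(curve, "progress_curve"))
  des <- curve$design
  if (des$ras_total > 0 || des$r1_initial > 0)
    stop_usage("curve must come from a RAS-free, r1-free design")
  P0 <- if (is.null(protease_total)) des$protease_total else protease_total
  S0 <- if (is.null(reporter_total)) des$reporter_total else reporter_total
  tt <- curve$time
  y <- curve$amc
  n <- length(y)

  # flat-curve guard: total rise must exceed noise by a clear margin
  m <- max(3L, n %/% 10L)
  rise <- mean(utils::tail(y, m)) - mean(utils::head(y, m))
  noise <- stats::sd(diff(y)) / sqrt(2)
  if (!is.finite(rise) || P0 <= 0 || rise < 5 * noise / sqrt(m) + 1e-15)
    stop_fit("progress curve is flat (or decreasing) beyond noise; cannot estimate a rate",
             diagnostics = list(rise = rise, noise = noise))

  # initial rate -> starting value for k
  j <- max(2L, n %/% 4L)
  k0 <- (y[j] - y[1]) / (tt[j] - tt[1]) / (S0 * P0)
  k0 <- min(max(k0, 1), 1e7)

  df <- data.frame(t = tt, y = y)
  fit <- tryCatch({
    if (baseline)
      minpack.lm::nlsLM(y ~ S0 * (1 - exp(-k * P0 * t)) + b, data = df,
                        start = list(k = k0, b = 0),
                        control = minpack.lm::nls.lm.control(maxiter = 200))
    else
      minpack.lm::nlsLM(y ~ S0 * (1 - exp(-k * P0 * t)), data = df,
                        start = list(k = k0),
                        control = minpack.lm::nls.lm.control(maxiter = 200))
  }, error = function(e) stop_fit(paste("exponential fit failed:",
                                        conditionMessage(e))))
  co <- summary(fit)$coefficients
  structure(list(k = co["k", "Estimate"], se = co["k", "Std. Error"],
                 baseline = if (baseline) co["b", "Estimate"] else 0,
                 fit = fit),
            class = "specificity_fit")
}

#' @export
print.specificity_fit <- function(x, ...) {
  cat(sprintf("Reporter specificity constant: %.4g +/- %.2g M^-1 s^-1\n",
              x$k, x$se))
  invisible(x)
}

# default box constraints (molar / s^-1 / M^-1 s^-1), generous but physical
default_bounds <- function() {
  list(K_S = c(1e-8, 1e-2), k_2 = c(1e-5, 1e3),
       K_P = c(1e-9, 1e-4), k_rep = c(1e2, 1e7))
}

#' Global fit of the cleavage mechanism to a suite of progress curves
#'
#' Minimises the total (weighted) squared residual over all curves of a suite
#' simultaneously, with `K_S`, `k_2`, `K_P` and `k_rep` shared across curves.
#' Optimisation is in log10-parameter space with box constraints, by
#' Levenberg-Marquardt from multiple starting points: `n_starts` log-uniform
#' draws (plus one data-driven start in which `k_rep` is pre-fit on a
#' RAS-free curve) are screened by their objective value and the best
#' `n_polish` are polished to convergence.  Any subset of parameters can be
#' held fixed — typically `K_P`, pinned by an independent product-fragment
#' titration (see [run_recovery_study()]).
#'
#' @param suite The [experiment_suite()] the curves belong to.
#' @param curves List of [progress_curve()] objects; each must carry a
#'   `design_index` attribute (as produced by [simulate_suite()]) or appear
#'   in the same order as `suite$designs`.  Several replicate curves may map
#'   to the same design.
#' @param init Optional named vector of starting values (natural units) for
#'   any of `K_S`, `k_2`, `K_P`, `k_rep`.
#' @param bounds Optional named list of length-2 lower/upper vectors.
#' @param fixed Optional named list of parameters to hold fixed.
#' @param weights Optional per-curve numeric weights (default unit weights).
#' @param n_starts Number of random multi-starts (default 20).
#' @param n_polish Number of screened starts polished to convergence
#'   (default 3).
#' @param seed Master seed for the start draws (default 1).
#' @return An object of class `fit_result` with elements `estimates`, `se`,
#'   `cov` (log10 scale, free parameters), `ratio` (= k_2/K_S exactly),
#'   `ratio_se`, `rss`, `df`, `residuals` (per curve), `fitted` (model curve
#'   per design), `starts` (log of all multi-starts), `rss_trace`
#'   (best-so-far objective across accepted iterations of the winning
#'   start), `fixed`, and convergence metadata.
#' @export
fit_global <- function(suite, curves, init = NULL, bounds = NULL,
                       fixed = NULL, weights = NULL, n_starts = 20,
                       n_polish = 3, seed = 1L) {
  stopifnot(inherits(suite, "experiment_suite"))
  if (inherits(curves, "progress_curve")) curves <- list(curves)
  idx <- vapply(seq_along(curves), function(i) {
    di <- attr(curves[[i]], "design_index")
    if (is.null(di)) i else as.integer(di)
  }, 1L)
  if (any(idx < 1L | idx > length(suite$designs)))
    stop_usage("curve design_index outside the suite's designs")
  if (is.null(weights)) weights <- rep(1, length(curves))

  pnames <- c("K_S", "k_2", "K_P", "k_rep")
  bnd <- default_bounds()
  if (!is.null(bounds)) bnd[names(bounds)] <- bounds
  fixed <- fixed[names(fixed) %in% pnames]
  free <- setdiff(pnames, names(fixed))
  if (!length(free)) stop_usage("at least one parameter must be free")

  assemble <- function(theta) {
    p <- numeric(4); names(p) <- pnames
    p[free] <- 10^theta
    for (nm in names(fixed)) p[nm] <- fixed[[nm]]
    p
  }
  used <- sort(unique(idx))
  obs <- lapply(curves, `[[`, "amc")
  npts <- sum(lengths(obs))

  model_curves <- function(p) {
    kp <- kinetic_params(p["K_S"], p["k_2"], p["K_P"], p["k_rep"])
    out <- vector("list", length(suite$designs))
    for (i in used)
      out[[i]] <- simulate_progress(suite$designs[[i]], kp)$amc
    out
  }
  resid_fun <- function(theta) {
    p <- assemble(theta)
    mc <- tryCatch(model_curves(p), error = function(e) NULL)
    if (is.null(mc)) return(rep(1e3, npts))
    unlist(lapply(seq_along(curves), function(j)
      (obs[[j]] - mc[[idx[j]]]) * weights[j]), use.names = FALSE)
  }

  # data-driven start: pre-fit k_rep on a RAS-free, r1-free curve if present
  start0 <- c(K_S = 5e-6, k_2 = sqrt(prod(bnd$k_2)),
              K_P = sqrt(prod(bnd$K_P)), k_rep = sqrt(prod(bnd$k_rep)))
  base_j <- which(vapply(idx, function(i)
    suite$designs[[i]]$ras_total == 0 && suite$designs[[i]]$r1_initial == 0,
    TRUE))
  if (length(base_j)) {
    kr <- tryCatch(estimate_specificity_constant(curves[[base_j[1]]])$k,
                   error = function(e) NA_real_)
    if (is.finite(kr)) start0["k_rep"] <- kr
  }
  if (!is.null(init)) start0[names(init)] <- init
  start0 <- pmin(pmax(start0, vapply(bnd, `[`, 0, 1)[pnames]),
                 vapply(bnd, `[`, 0, 2)[pnames])

  lower <- log10(vapply(bnd[free], `[`, 0, 1))
  upper <- log10(vapply(bnd[free], `[`, 0, 2))
  starts <- matrix(NA_real_, n_starts + 1L, length(free),
                   dimnames = list(NULL, free))
  starts[1L, ] <- log10(start0[free])
  if (n_starts > 0) {
    draws <- with_local_seed(seed, matrix(
      stats::runif(n_starts * length(free), rep(lower, each = n_starts),
                   rep(upper, each = n_starts)), n_starts))
    starts[-1L, ] <- draws
  }

  rss0 <- apply(starts, 1L, function(th) sum(resid_fun(th)^2))
  ord <- order(rss0)
  polish <- ord[seq_len(min(n_polish, nrow(starts)))]

  fits <- lapply(polish, function(r) {
    tryCatch(minpack.lm::nls.lm(
      par = starts[r, ], lower = lower, upper = upper, fn = resid_fun,
      control = minpack.lm::nls.lm.control(ftol = 1e-12, ptol = 1e-12,
                                           maxiter = 300)),
      error = function(e) NULL)
  })
  ok <- !vapply(fits, is.null, TRUE)
  if (!any(ok))
    stop_fit("all polished multi-starts failed to converge",
             diagnostics = list(start_rss = rss0))
  rss_fin <- vapply(fits, function(f) if (is.null(f)) Inf else f$deviance, 0)
  best <- which.min(rss_fin)
  fit <- fits[[best]]

  theta <- fit$par
  est <- assemble(theta)
  rss <- fit$deviance
  dfree <- npts - length(free)
  sigma2 <- rss / dfree

  # covariance of the free log10 parameters from a numerical Jacobian
  J <- num_jacobian(resid_fun, theta)
  JtJ <- crossprod(J)
  covl <- tryCatch(sigma2 * solve(JtJ), error = function(e) {
    sv <- svd(JtJ)
    pos <- sv$d > max(sv$d) * 1e-12
    sigma2 * sv$v[, pos, drop = FALSE] %*%
      (t(sv$u[, pos, drop = FALSE]) / sv$d[pos])
  })
  dimnames(covl) <- list(free, free)
  se <- stats::setNames(rep(0, 4), pnames)
  se[free] <- log(10) * est[free] * sqrt(pmax(diag(covl), 0))

  ratio <- est[["k_2"]] / est[["K_S"]]
  ratio_se <- NA_real_
  if (all(c("K_S", "k_2") %in% free)) {
    v <- covl["k_2", "k_2"] + covl["K_S", "K_S"] - 2 * covl["k_2", "K_S"]
    ratio_se <- ratio * log(10) * sqrt(max(v, 0))
  } else if ("k_2" %in% free) {
    ratio_se <- ratio * log(10) * sqrt(max(covl["k_2", "k_2"], 0))
  }

  mc <- model_curves(est)
  residuals <- lapply(seq_along(curves), function(j) obs[[j]] - mc[[idx[j]]])

  starts_log <- data.frame(start = seq_len(nrow(starts)), 10^starts,
                           rss_start = rss0,
                           polished = seq_len(nrow(starts)) %in% polish)
  starts_log$rss_final <- NA_real_
  starts_log$rss_final[polish] <- rss_fin

  structure(list(estimates = est, se = se, cov = covl, ratio = ratio,
                 ratio_se = ratio_se, rss = rss, df = dfree,
                 sigma2 = sigma2, residuals = residuals, fitted = mc,
                 curve_index = idx, starts = starts_log,
                 rss_trace = fit$rsstrace, free = free, fixed = fixed,
                 bounds = bnd, info = fit$info, message = fit$message,
                 niter = fit$niter, seed = seed, suite_label = suite$label),
            class = "fit_result")
}

num_jacobian <- function(fn, theta, h = 1e-6) {
  f0 <- fn(theta)
  J <- matrix(0, length(f0), length(theta))
  for (j in seq_along(theta)) {
    tp <- theta
    tp[j] <- tp[j] + h
    J[, j] <- (fn(tp) - f0) / h
  }
  J
}

#' @export
print.fit_result <- function(x, ...) {
  cat(sprintf("Global fit of suite '%s' (%d curves, rss = %.4g, %d iter)\n",
              x$suite_label, length(x$residuals), x$rss, x$niter))
  for (nm in names(x$estimates)) {
    tag <- if (nm %in% names(x$fixed)) " (fixed)" else
      sprintf(" +/- %.3g", x$se[[nm]])
    cat(sprintf("  %-5s = %.5g%s\n", nm, x$estimates[[nm]], tag))
  }
  cat(sprintf("  k_2/K_S = %.5g", x$ratio))
  if (is.finite(x$ratio_se)) cat(sprintf(" +/- %.3g", x$ratio_se))
  cat(" M^-1 s^-1\n")
  invisible(x)
}

#' Profile-likelihood interval for the specificity constant
#'
#' Profiles the residual sum of squares over the derived ratio
#' `rho = k_2/K_S`: for each value of `rho` on a logarithmic grid the
#' remaining free parameters are re-optimised (with `k_2 = rho * K_S`), and
#' the interval is the set of `rho` whose profiled RSS stays below
#' \deqn{RSS_{min}\,(1 + F_{1,df}(level)/df).}
#' The grid half-width adapts to the local curvature and expands (up to a
#' cap) until both crossings are bracketed; a side that never crosses is
#' flagged unbounded.
#'
#' @param fit A converged [fit_global()] result.
#' @param suite,curves The suite and curves the fit was computed from.
#' @param level Confidence level (default 0.95).
#' @param n_grid Grid points per side (default 8).
#' @return List with `lower`, `upper` (M^-1 s^-1), `estimate`, `level`,
#'   `unbounded` (logical pair), and the profile grid as a data frame.
#' @export
profile_specificity <- function(fit, suite, curves, level = 0.95,
                                n_grid = 8) {
  stopifnot(inherits(fit, "fit_result"))
  if (!"k_2" %in% fit$free)
    stop_usage("k_2 must be a free parameter to profile the ratio")
  if (inherits(curves, "progress_curve")) curves <- list(curves)
  idx <- fit$curve_index
  obs <- lapply(curves, `[[`, "amc")
  npts <- sum(lengths(obs))
  used <- sort(unique(idx))

  other <- setdiff(fit$free, "k_2") # K_S stays free; k_2 is slaved to rho
  bnd <- fit$bounds
  lower <- log10(vapply(bnd[other], `[`, 0, 1))
  upper <- log10(vapply(bnd[other], `[`, 0, 2))

  resid_rho <- function(lrho, th_other) {
    p <- numeric(4); names(p) <- c("K_S", "k_2", "K_P", "k_rep")
    p[other] <- 10^th_other
    for (nm in names(fit$fixed)) p[nm] <- fit$fixed[[nm]]
    p["k_2"] <- 10^lrho * p["K_S"]
    mc <- tryCatch({
      kp <- kinetic_params(p["K_S"], p["k_2"], p["K_P"], p["k_rep"])
      lapply(used, function(i) simulate_progress(suite$designs[[i]], kp)$amc)
    }, error = function(e) NULL)
    if (is.null(mc)) return(rep(1e3, npts))
    names(mc) <- used
    unlist(lapply(seq_along(curves), function(j)
      obs[[j]] - mc[[as.character(idx[j])]]), use.names = FALSE)
  }

  prof_rss <- function(lrho, th_start) {
    f <- tryCatch(minpack.lm::nls.lm(
      par = th_start, lower = lower, upper = upper,
      fn = function(th) resid_rho(lrho, th),
      control = minpack.lm::nls.lm.control(ftol = 1e-12, ptol = 1e-12,
                                           maxiter = 200)),
      error = function(e) NULL)
    if (is.null(f)) list(rss = Inf, par = th_start)
    else list(rss = f$deviance, par = f$par)
  }

  lrho0 <- log10(fit$ratio)
  thr <- fit$rss * (1 + stats::qf(level, 1, fit$df) / fit$df)
  se_l <- if (is.finite(fit$ratio_se) && fit$ratio_se > 0)
    fit$ratio_se / fit$ratio / log(10) else 1e-4
  w <- max(3 * se_l, 1e-5)

  th0 <- log10(fit$estimates[other])
  walk <- function(sign) {
    for (trial in 1:5) {
      grid <- lrho0 + sign * w * seq(1 / n_grid, 1, length.out = n_grid)
      rss <- numeric(n_grid)
      th <- th0
      for (g in seq_len(n_grid)) {
        pr <- prof_rss(grid[g], th)
        rss[g] <- pr$rss
        th <- pr$par
        if (rss[g] > thr) {
          xs <- c(if (g == 1) lrho0 else grid[g - 1], grid[g])
          ys <- c(if (g == 1) fit$rss else rss[g - 1], rss[g])
          cross <- xs[1] + (thr - ys[1]) / (ys[2] - ys[1]) * diff(xs)
          return(list(bound = 10^cross, unbounded = FALSE,
                      grid = data.frame(log10_ratio = grid[1:g],
                                        rss = rss[1:g])))
        }
      }
      w <<- w * 4
      if (w > 3) break # more than three decades: treat as unidentifiable
    }
    list(bound = if (sign < 0) 0 else Inf, unbounded = TRUE,
         grid = data.frame(log10_ratio = numeric(), rss = numeric()))
  }
  lo <- walk(-1)
  hi <- walk(+1)
  list(lower = lo$bound, upper = hi$bound, estimate = fit$ratio,
       level = level, unbounded = c(lower = lo$unbounded, upper = hi$unbounded),
       grid = rbind(lo$grid, hi$grid))
}

#' Selectivity ratio between two fitted forms
#'
#' The fold preference of the protease for active over inactive RAS:
#' `(k_2/K_S)_active / (k_2/K_S)_inactive`.
#'
#' @param fit_active,fit_inactive Converged [fit_global()] results (or any
#'   objects with a finite `ratio` element).
#' @return Dimensionless fold preference.
#' @examples
#' selectivity_ratio(list(ratio = 13720), list(ratio = 220)) # ~62
#' @export
selectivity_ratio <- function(fit_active, fit_inactive) {
  ra <- fit_active$ratio
  ri <- fit_inactive$ratio
  if (!is.finite(ra) || !is.finite(ri) || ri == 0)
    stop_domain("selectivity ratio needs finite, nonzero specificity constants")
  ra / ri
}
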