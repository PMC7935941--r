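#' Free protease concentration under rapid-equilibrium binding
#'
#' Partitions total protease between the free enzyme, the protease-RAS
#' complex and the protease-r1 product complex, assuming both binding steps
#' are at equilibrium.  Solves the conservation equation
#' \deqn{P \left(1 + \frac{R_t}{K_S + P} + \frac{r1_t}{K_P + P}\right) = P_{tot}}
#' for the free protease `P` by safeguarded Newton iteration on the monotone
#' residual, bracketed on `[0, protease_total]`.
#'
#' @param protease_total Total protease (M).
#' @param ras_intact_total Total intact RAS, free plus bound (M).
#' @param r1_total Total r1 product fragment, free plus bound (M).
#' @param K_S Dissociation constant of the protease-RAS complex (M).
#' @param K_P Dissociation constant of the protease-r1 complex (M).
#'
#' @return Free protease concentration (M), in `[0, protease_total]`, with a
#'   relative residual below 1e-10.
#' @examples
#' free_protease(1e-7, 1e-6, 1e-6, 1e-6, 1e-6)
#' @export
free_protease <- function(protease_total, ras_intact_total, r1_total,
                          K_S, K_P) {
  args <- c(protease_total = protease_total,
            ras_intact_total = ras_intact_total, r1_total = r1_total,
            K_S = K_S, K_P = K_P)
  if (any(!is.finite(args)) || any(args < 0))
    stop_domain("all arguments to free_protease() must be finite and non-negative")
  if (K_S <= 0 || K_P <= 0)
    stop_domain("dissociation constants must be strictly positive")
  .Call(rascleave_free_p_call, as.numeric(protease_total),
        as.numeric(ras_intact_total), as.numeric(r1_total),
        as.numeric(K_S), as.numeric(K_P))
}

#' Time derivatives of the cleavage mechanism
#'
#' Evaluates the right-hand side of the mechanism at one state, in either of
#' two reductions:
#' \describe{
#'   \item{`rapid_equilibrium`}{Both binding steps are at equilibrium; free
#'     protease is obtained from [free_protease()], the cleavage flux is
#'     `k_2 * [RP]`, and the reporter flux is `k_rep * P_free * S`.}
#'   \item{`mass_action`}{Binding steps are explicit with on-rate `k_on` and
#'     off-rates `k_on * K_S` and `k_on * K_P`; acylation converts `RP` to
#'     `Pr1 + r2` at `k_2`.}
#' }
#' This pure-R evaluation is the reference implementation; simulation uses a
#' compiled version of the same equations.
#'
#' @param state Named numeric vector with elements `R`, `P`, `RP`, `Pr1`,
#'   `S`, `r1`, `r2`, `AMC` (M).  In rapid-equilibrium mode the complexes are
#'   re-derived from the totals, so only the conservation totals matter.
#' @param params A [kinetic_params()] object.
#' @param design An [assay_design()] object (supplies the conservation
#'   totals).
#' @param mode `"rapid_equilibrium"` or `"mass_action"`.
#'
#' @return Named numeric vector of time derivatives for all eight species
#'   (M/s).  Derivatives sum to zero within each conservation group.
#' @export
mechanism_rhs <- function(state, params, design,
                          mode = c("rapid_equilibrium", "mass_action")) {
  if (is.character(mode) && length(mode) == 1 &&
      !mode %in% c("rapid_equilibrium", "mass_action"))
    stop_usage(sprintf("unknown mode '%s'", mode))
  mode <- match.arg(mode)
  stopifnot(inherits(params, "kinetic_params"), inherits(design, "assay_design"))
  need <- c("R", "P", "RP", "Pr1", "S", "r1", "r2", "AMC")
  if (!all(need %in% names(state)))
    stop_usage("state must contain R, P, RP, Pr1, S, r1, r2, AMC")
  s <- state[need]

  if (mode == "rapid_equilibrium") {
    Rt <- s[["R"]] + s[["RP"]]
    r1t <- s[["r1"]] + s[["Pr1"]]
    P <- free_protease(design$protease_total, Rt, r1t, params$K_S, params$K_P)
    RP <- Rt * P / (params$K_S + P)
    acyl <- params$k_2 * RP
    rep <- params$k_rep * P * s[["S"]]
    # Under the equilibrium reduction only the pool totals are dynamical;
    # the pool fluxes are reported on the free species (complexes are slaved
    # to the equilibrium constraint) so each conservation group sums to zero.
    return(c(R = -acyl, P = 0, RP = 0, Pr1 = 0, S = -rep, r1 = acyl,
             r2 = acyl, AMC = rep))
  }

  kon <- params$k_on
  bindS <- kon * s[["R"]] * s[["P"]] - kon * params$K_S * s[["RP"]]
  bindP <- kon * s[["r1"]] * s[["P"]] - kon * params$K_P * s[["Pr1"]]
  acyl <- params$k_2 * s[["RP"]]
  rep <- params$k_rep * s[["P"]] * s[["S"]]
  c(R = -bindS, P = -bindS - bindP, RP = bindS - acyl, Pr1 = acyl + bindP,
    S = -rep, r1 = -bindP, r2 = acyl, AMC = rep)
}

#' Simulate a progress curve
#'
#' Integrates the cleavage mechanism over the design's time grid and returns
#' the AMC progress curve together with the full species trajectory.  The
#' rapid-equilibrium reduction integrates two state variables (intact RAS and
#' uncleaved reporter) and reconstructs all eight species algebraically; the
#' mass-action mode integrates all eight.  Integration uses a stiff-capable
#' solver (`lsoda`) with relative tolerance 1e-10 and absolute tolerance
#' 1e-16 M; small negative concentrations within tolerance are clipped at 0.
#'
#' @inheritParams mechanism_rhs
#' @param design An [assay_design()].
#' @param params A [kinetic_params()].
#' @param compiled Use the compiled right-hand side (default) or the pure-R
#'   reference implementation.
#'
#' @return A [progress_curve()] whose `trajectory` attribute is a data frame
#'   with columns `time`, `R`, `P`, `RP`, `Pr1`, `S`, `r1`, `r2`, `AMC`
#'   (all molar).
#' @examples
#' des <- assay_design(1e-7, 0, "none", 1e-6, 0, "imidazole", 1e-3,
#'                     seq(0, 500, by = 50))
#' kp <- kinetic_params(5e-6, 0.0686, 4e-7, 2e4)
#' simulate_progress(des, kp)
#' @export
simulate_progress <- function(design, params,
                              mode = c("rapid_equilibrium", "mass_action"),
                              compiled = TRUE) {
  mode <- match.arg(mode)
  stopifnot(inherits(design, "assay_design"), inherits(params, "kinetic_params"))
  times <- design$time_grid

  if (mode == "rapid_equilibrium") {
    y0 <- c(Rt = design$ras_total, S = design$reporter_total)
    parms <- c(design$protease_total, design$ras_total, design$r1_initial,
               params$K_S, params$k_2, params$K_P, params$k_rep)
    if (compiled) {
      out <- deSolve::lsoda(y0, times, func = "rascleave_derivs_re",
                            parms = parms, dllname = "rascleave",
                            initfunc = "rascleave_init_re",
                            rtol = 1e-10, atol = 1e-16)
    } else {
      rhs <- function(t, y, p) {
        Rt <- max(y[1], 0); S <- max(y[2], 0)
        r1t <- design$ras_total + design$r1_initial - Rt
        P <- free_protease(design$protease_total, Rt, r1t,
                           params$K_S, params$K_P)
        RP <- Rt * P / (params$K_S + P)
        list(c(-params$k_2 * RP, -params$k_rep * P * S))
      }
      out <- deSolve::lsoda(y0, times, rhs, NULL, rtol = 1e-10, atol = 1e-16)
    }
    check_solver(out, times)
    Rt <- clip0(out[, "Rt"]); S <- clip0(pmin(out[, "S"], design$reporter_total))
    traj <- re_trajectory(times, Rt, S, design, params)
  } else {
    y0 <- c(R = design$ras_total, P = design$protease_total, RP = 0, Pr1 = 0,
            S = design$reporter_total, r1 = design$r1_initial, r2 = 0, AMC = 0)
    parms <- c(params$K_S, params$k_2, params$K_P, params$k_rep, params$k_on)
    if (compiled) {
      out <- deSolve::lsoda(y0, times, func = "rascleave_derivs_ma",
                            parms = parms, dllname = "rascleave",
                            initfunc = "rascleave_init_ma",
                            rtol = 1e-10, atol = 1e-16, maxsteps = 50000)
    } else {
      rhs <- function(t, y, p) {
        names(y) <- names(y0)
        list(unname(mechanism_rhs(y, params, design, "mass_action")))
      }
      out <- deSolve::lsoda(y0, times, rhs, NULL, rtol = 1e-10, atol = 1e-16,
                            maxsteps = 50000)
    }
    check_solver(out, times)
    traj <- as.data.frame(out)
    names(traj)[1] <- "time"
    traj[-1] <- lapply(traj[-1], clip0)
  }

  amc <- cummax(clip0(traj$AMC)) # enforce monotonicity against solver jitter
  curve <- progress_curve(times, amc, design, noise_sigma = 0)
  attr(curve, "trajectory") <- traj
  attr(curve, "mode") <- mode
  curve
}

# reconstruct the full species set from the reduced rapid-equilibrium state
re_trajectory <- function(times, Rt, S, design, params) {
  n <- length(times)
  P <- numeric(n); RP <- numeric(n); Pr1 <- numeric(n)
  r1t <- design$ras_total + design$r1_initial - Rt
  for (i in seq_len(n)) {
    P[i] <- free_protease(design$protease_total, Rt[i], r1t[i],
                          params$K_S, params$K_P)
    RP[i] <- Rt[i] * P[i] / (params$K_S + P[i])
    Pr1[i] <- r1t[i] * P[i] / (params$K_P + P[i])
  }
  data.frame(time = times, R = clip0(Rt - RP), P = P, RP = RP, Pr1 = Pr1,
             S = S, r1 = clip0(r1t - Pr1), r2 = clip0(design$ras_total - Rt),
             AMC = clip0(design$reporter_total - S))
}

check_solver <- function(out, times) {
  if (nrow(out) < length(times) || any(!is.finite(out)))
    stop_numerical("ODE solver failed to cover the requested time grid",
                   diagnostics = attributes(out)[c("istate", "rstate")])
  invisible(out)
}

clip0 <- function(x) pmax(x, 0)

#' Export a species trajectory to CSV
#'
#' Writes the full state trajectory of one or more simulated curves as a flat
#' CSV with columns `curve_id`, `time_s`, and one column per species (molar).
#'
#' @param curves A `progress_curve` with a trajectory attribute, or a list of
#'   them.
#' @param path Output file path.
#' @return The path, invisibly.
#' @export
write_trajectory <- function(curves, path) {
  if (inherits(curves, "progress_curve")) curves <- list(curves)
  rows <- lapply(seq_along(curves), function(i) {
    cv <- curves[[i]]
    traj <- attr(cv, "trajectory")
    if (is.null(traj))
      stop_usage("curve has no stored trajectory; simulate it first")
    id <- if (is.na(cv$curve_id)) sprintf("curve_%02d", i) else cv$curve_id
    cbind(curve_id = id, stats::setNames(traj, c("time_s", names(traj)[-1])))
  })
  utils::write.csv(do.call(rbind, rows), path, row.names = FALSE)
  invisible(path)
}
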