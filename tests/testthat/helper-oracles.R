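# Independent oracles used to pin expected values; deliberately written
# without reference to the package internals.

# bisection on the protease conservation residual over [0, Ptot]
oracle_free_p <- function(Ptot, Rt, r1t, KS, KP, iter = 200) {
  if (Ptot <= 0) return(0)
  f <- function(P) P * (1 + Rt / (KS + P) + r1t / (KP + P)) - Ptot
  lo <- 0
  hi <- Ptot
  for (i in seq_len(iter)) {
    mid <- 0.5 * (lo + hi)
    if (f(mid) > 0) hi <- mid else lo <- mid
  }
  0.5 * (lo + hi)
}

# single-exponential reporter consumption when no RAS or r1 is present
oracle_closed_form <- function(S0, k_rep, Ptot, t) {
  S0 * (1 - exp(-k_rep * Ptot * t))
}

# small, fast fixtures
quick_params <- function(...) {
  args <- utils::modifyList(
    list(K_S = 5e-6, k_2 = 0.0686, K_P = 4e-7, k_rep = 2e4), list(...))
  do.call(kinetic_params, args)
}

quick_design <- function(ras = 5e-6, r1 = 0, S0 = 1e-6, P0 = 1e-7,
                         t_end = 2000, n = 41) {
  assay_design(P0, ras, if (ras > 0) "active" else "none", S0, r1,
               "imidazole", 1e-3, seq(0, t_end, length.out = n))
}

with_seed_vec <- function(seed, n, sd) {
  set.seed(seed)
  rnorm(n, 0, sd)
}

# conservation drift of a simulated trajectory, relative to initial pools
conservation_drift <- function(curve) {
  tr <- attr(curve, "trajectory")
  des <- curve$design
  prot <- tr$P + tr$RP + tr$Pr1
  ras <- tr$R + tr$RP + tr$r1 + tr$Pr1
  rep <- tr$S + tr$AMC
  stoich <- tr$r1 + tr$Pr1 - des$r1_initial - tr$r2
  scale <- c(max(des$protease_total, 1e-12), max(des$ras_total + des$r1_initial, 1e-12),
             max(des$reporter_total, 1e-12), max(des$ras_total + des$r1_initial, 1e-12))
  c(protease = max(abs(prot - des$protease_total)) / scale[1],
    ras = max(abs(ras - (des$ras_total + des$r1_initial))) / scale[2],
    reporter = max(abs(rep - des$reporter_total)) / scale[3],
    stoichiometry = max(abs(stoich)) / scale[4])
}
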