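#' Read a curve table from CSV
#'
#' Reads a flat table of progress curves with the exact header
#' `curve_id,time_s,signal`.  Within each `curve_id` the times must be
#' strictly increasing and every cell must be present and numeric; violations
#' raise a parse error naming the offending row.
#'
#' @param path CSV file path.
#' @return A data frame of class `curve_table` with columns `curve_id`
#'   (character), `time_s`, `signal` (numeric).
#' @export
read_curves <- function(path) {
  if (!file.exists(path)) stop_usage(sprintf("no such file: %s", path))
  raw <- utils::read.csv(path, colClasses = "character", check.names = FALSE)
  if (!identical(names(raw), c("curve_id", "time_s", "signal")))
    stop_usage("curve table header must be exactly: curve_id,time_s,signal")
  tab <- data.frame(curve_id = raw$curve_id,
                    time_s = suppressWarnings(as.numeric(raw$time_s)),
                    signal = suppressWarnings(as.numeric(raw$signal)),
                    stringsAsFactors = FALSE)
  bad <- which(is.na(tab$time_s) | is.na(tab$signal) | tab$curve_id == "")
  if (length(bad))
    stop_usage(sprintf("non-numeric or missing cell at data row %d", bad[1]))
  for (id in unique(tab$curve_id)) {
    tt <- tab$time_s[tab$curve_id == id]
    w <- which(diff(tt) <= 0)
    if (length(w))
      stop_usage(sprintf(
        "times not strictly increasing in curve '%s' (data row %d)", id,
        which(tab$curve_id == id)[w[1] + 1L]))
  }
  class(tab) <- c("curve_table", "data.frame")
  tab
}

#' Write a curve table (or list of curves) to CSV
#'
#' @param table A `curve_table` data frame, or a list of
#'   [progress_curve()] objects (converted with [curves_to_table()]).
#' @param path Output CSV path.
#' @return The path, invisibly.
#' @export
write_curves <- function(table, path) {
  if (is.list(table) && !is.data.frame(table))
    table <- curves_to_table(table)
  if (!all(c("curve_id", "time_s", "signal") %in% names(table)))
    stop_usage("table must have columns curve_id, time_s, signal")
  utils::write.csv(table[c("curve_id", "time_s", "signal")], path,
                   row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Flatten progress curves into a curve table
#'
#' @param curves List of [progress_curve()] objects.
#' @return A `curve_table` data frame.
#' @export
curves_to_table <- function(curves) {
  if (inherits(curves, "progress_curve")) curves <- list(curves)
  rows <- lapply(seq_along(curves), function(i) {
    cv <- curves[[i]]
    id <- if (is.na(cv$curve_id)) sprintf("curve_%02d", i) else cv$curve_id
    data.frame(curve_id = id, time_s = cv$time, signal = cv$amc)
  })
  tab <- do.call(rbind, rows)
  class(tab) <- c("curve_table", "data.frame")
  tab
}

#' Read / write a configuration document
#'
#' Configuration documents are JSON (or YAML, if the `yaml` package is
#' available) holding truth parameters, suite definitions, the noise model,
#' fit options and turnover parameters.  Unknown fields are preserved.
#'
#' @param path File path; format inferred from the extension
#'   (`.json`, `.yaml`, `.yml`).
#' @return A named list.
#' @export
read_config <- function(path) {
  if (!file.exists(path)) stop_usage(sprintf("no such file: %s", path))
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("yaml", "yml")) {
    if (!requireNamespace("yaml", quietly = TRUE))
      stop_usage("the 'yaml' package is required to read YAML configs")
    yaml::read_yaml(path)
  } else {
    jsonlite::read_json(path, simplifyVector = TRUE)
  }
}

#' @rdname read_config
#' @param config Named list to serialise.
#' @export
write_config <- function(config, path) {
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("yaml", "yml")) {
    if (!requireNamespace("yaml", quietly = TRUE))
      stop_usage("the 'yaml' package is required to write YAML configs")
    yaml::write_yaml(config, path)
  } else {
    jsonlite::write_json(config, path, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE)
  }
  invisible(path)
}

#' Generate, fit, and score a parameter-recovery study
#'
#' The end-to-end pipeline: build the product-fragment (r1) titration suite
#' and the RAS titration suite for one protease/cofactor pair under
#' generator-truth parameters, simulate seeded noisy curves, and run the
#' staged global fit —
#' \enumerate{
#'   \item `k_rep` is pre-fit on a RAS-free curve (used as a starting value),
#'   \item `K_P` and `k_rep` are estimated from the r1-titration suite
#'     (`K_S` and `k_2` do not enter its likelihood and are held fixed),
#'   \item the RAS-titration suite is fit globally for `K_S`, `k_2` and
#'     `k_rep` with `K_P` fixed at the stage-2 estimate,
#' }
#' mirroring the experimental logic in which the product dissociation
#' constant is measured in an independent series of experiments.  Truth and
#' estimates are reported for every parameter and for the specificity
#' constant k_2/K_S.
#'
#' @param config Named list (or path to a JSON/YAML file) with fields:
#'   `protease` (`"imidazole"` or `"nitrite"`), `ras_form` (`"active"` or
#'   `"inactive"`), `noise_sigma` (fraction of reporter, default 0.01),
#'   `seed` (default 1), `replicates` (noisy replicates per design, default
#'   3), `n_starts` (default 20), `n_polish` (default 3), and optionally
#'   `truth` (named list overriding [default_truth()]).
#' @param out_dir Optional directory; when given, the resolved config, the
#'   simulated curves (CSV) and the fit report (JSON) are written there.
#' @return An object of class `recovery_report`: lists `truth`, `estimates`,
#'   `relative_error`, the two `fit_result`s (`fit_kp`, `fit_ras`), the
#'   simulated curves, and the resolved config.
#' @export
run_recovery_study <- function(config, out_dir = NULL) {
  if (is.character(config)) config <- read_config(config)
  cfg <- list(protease = "imidazole", ras_form = "active",
              noise_sigma = 0.01, seed = 1L, replicates = 3L,
              n_starts = 20L, n_polish = 3L)
  cfg[names(config)] <- config
  truth <- default_truth(cfg$protease, cfg$ras_form)
  if (!is.null(cfg$truth)) {
    over <- cfg$truth
    truth <- kinetic_params(
      K_S = over$K_S %||% truth$K_S, k_2 = over$k_2 %||% truth$k_2,
      K_P = over$K_P %||% truth$K_P, k_rep = over$k_rep %||% truth$k_rep)
  }
  nm <- noise_model(cfg$noise_sigma, as.integer(cfg$seed))

  kp_suite <- build_kp_titration_suite(truth, cfg$protease, noise = nm)
  ras_suite <- build_ras_titration_suite(cfg$ras_form, truth, cfg$protease,
                                         noise = nm)
  kp_curves <- simulate_suite(kp_suite, noisy = nm$sigma > 0, replicates = 1)
  ras_curves <- simulate_suite(ras_suite, noisy = nm$sigma > 0,
                               replicates = cfg$replicates)

  # stage 2: K_P and k_rep from the product titration (K_S, k_2 inert there)
  fit_kp <- fit_global(kp_suite, kp_curves,
                       fixed = list(K_S = truth$K_S, k_2 = truth$k_2),
                       n_starts = cfg$n_starts, n_polish = cfg$n_polish,
                       seed = as.integer(cfg$seed))
  # stage 3: RAS suite with K_P pinned
  fit_ras <- fit_global(ras_suite, ras_curves,
                        fixed = list(K_P = fit_kp$estimates[["K_P"]]),
                        n_starts = cfg$n_starts, n_polish = cfg$n_polish,
                        seed = as.integer(cfg$seed) + 1L)

  est <- c(fit_ras$estimates[c("K_S", "k_2")],
           K_P = fit_kp$estimates[["K_P"]],
           k_rep = fit_ras$estimates[["k_rep"]],
           specificity = fit_ras$ratio)
  tru <- c(K_S = truth$K_S, k_2 = truth$k_2, K_P = truth$K_P,
           k_rep = truth$k_rep, specificity = specificity_constant(truth))
  rel <- est / tru - 1

  report <- structure(list(config = cfg, truth = tru, estimates = est,
                           relative_error = rel, fit_kp = fit_kp,
                           fit_ras = fit_ras, kp_suite = kp_suite,
                           ras_suite = ras_suite, kp_curves = kp_curves,
                           ras_curves = ras_curves),
                      class = "recovery_report")
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    write_config(cfg, file.path(out_dir, "config.json"))
    write_curves(c(kp_curves, ras_curves), file.path(out_dir, "curves.csv"))
    write_fit_report(report, file.path(out_dir, "fit_report.json"))
  }
  report
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.recovery_report <- function(x, ...) {
  cat(sprintf("Recovery study: %s protease, %s RAS, noise %.3g%%, seed %d\n",
              x$config$protease, x$config$ras_form,
              100 * x$config$noise_sigma, x$config$seed))
  tab <- data.frame(truth = signif(x$truth, 5),
                    estimate = signif(x$estimates, 5),
                    rel_error = sprintf("%+.2f%%", 100 * x$relative_error))
  print(tab)
  invisible(x)
}

#' Write a fit report as JSON
#'
#' Serialises estimates, uncertainties, residual summaries, seeds and the
#' multi-start log of a recovery study (or single fit) to a JSON document.
#'
#' @param report A `recovery_report` or `fit_result`.
#' @param path Output path.
#' @return The path, invisibly.
#' @export
write_fit_report <- function(report, path) {
  strip_fit <- function(f) list(
    estimates = as.list(f$estimates), se = as.list(f$se),
    ratio = f$ratio, ratio_se = f$ratio_se, rss = f$rss, df = f$df,
    residual_sd_per_curve = vapply(f$residuals, stats::sd, 0),
    fixed = f$fixed, niter = f$niter, info = f$info, message = f$message,
    seed = f$seed, starts = f$starts)
  doc <- if (inherits(report, "recovery_report")) {
    list(config = report$config, truth = as.list(report$truth),
         estimates = as.list(report$estimates),
         relative_error = as.list(report$relative_error),
         fit_kp = strip_fit(report$fit_kp),
         fit_ras = strip_fit(report$fit_ras))
  } else strip_fit(report)
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, force = TRUE)
  invisible(path)
}

#' Fitted-versus-observed export for plotting
#'
#' Flattens a fit into a long table of observed and fitted signals plus
#' residuals, one row per observation, mirroring the usual layout of
#' progress-curve figures (fit line through the data, residual panel above).
#'
#' @param fit A [fit_global()] result.
#' @param curves The curves the fit was computed from.
#' @return Data frame with columns `curve_id`, `time_s`, `observed`,
#'   `fitted`, `residual`.
#' @export
fitted_table <- function(fit, curves) {
  stopifnot(inherits(fit, "fit_result"))
  if (inherits(curves, "progress_curve")) curves <- list(curves)
  rows <- lapply(seq_along(curves), function(j) {
    cv <- curves[[j]]
    id <- if (is.na(cv$curve_id)) sprintf("curve_%02d", j) else cv$curve_id
    data.frame(curve_id = id, time_s = cv$time, observed = cv$amc,
               fitted = fit$fitted[[fit$curve_index[j]]],
               residual = fit$residuals[[j]])
  })
  do.call(rbind, rows)
}
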