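#' Configuration of the Monte-Carlo estimator study
#'
#' Bundles the simulation conditions for the precision/bias experiments:
#' tissue-like BP levels (low/moderate/high receptor expression), the fixed
#' BP used in the nonspecific-binding sweep, the nonspecific rate sweep,
#' measurement noise, iteration count and the acquisition schedule.
#'
#' @param bp_levels generating BP levels for the recovery study
#'   (default \code{c(0.0005, 1, 3)}: healthy-, U251- and A431-like).
#' @param bp_fixed_for_sweep BP held fixed during the nonspecific-binding
#'   sweep (default 2.17, the tissue-average high-expression value).
#' @param k5_sweep nonspecific association rates (min^-1) for the sweep;
#'   default gives \code{k5/k6} ratios 0, 0.5, 1, 1.5, 2, 2.667, 3.5, 5.
#' @param k6 nonspecific dissociation rate (min^-1, default 0.06).
#' @param k5_default nonspecific association rate for the recovery study
#'   (min^-1, default 0.16; \code{k5/k6 = 2.67}).
#' @param k4 specific dissociation rate (min^-1, default 0.1; a
#'   literature-consistent EGFR dissociation value, not separately
#'   verifiable). Fixed in the targeted fits.
#' @param F_washout rinse washout rate (min^-1, default 2.0: one 0.5-min
#'   rinse cycle removes ~63\% of free probe).
#' @param noise_percent Gaussian measurement noise as \% of clean-curve RMS
#'   (default 0.48).
#' @param n_iterations Monte-Carlo replicates per condition (default 100).
#' @param schedule an \code{\link{acquisition_schedule}}.
#' @param seed root RNG seed; all per-iteration seeds derive from it.
#' @return An object of class \code{"simulation_config"}.
#' @export
simulation_config <- function(bp_levels = c(0.0005, 1, 3),
                              bp_fixed_for_sweep = 2.17,
                              k5_sweep = c(0, 0.5, 1, 1.5, 2, 8/3, 3.5, 5) * 0.06,
                              k6 = 0.06, k5_default = 0.16, k4 = 0.1,
                              F_washout = 2.0, noise_percent = 0.48,
                              n_iterations = 100L,
                              schedule = acquisition_schedule(),
                              seed = 1L) {
  stopifnot(n_iterations >= 1, all(bp_levels >= 0), all(k5_sweep >= 0),
            k6 >= 0, k5_default >= 0, k4 > 0, F_washout >= 0,
            noise_percent >= 0,
            inherits(schedule, "acquisition_schedule"))
  structure(list(bp_levels = bp_levels,
                 bp_fixed_for_sweep = bp_fixed_for_sweep,
                 k5_sweep = k5_sweep, k6 = k6, k5_default = k5_default,
                 k4 = k4, F_washout = F_washout,
                 noise_percent = noise_percent,
                 n_iterations = as.integer(n_iterations),
                 schedule = schedule, seed = as.integer(seed)),
            class = "simulation_config")
}

# Independent per-condition/iteration seeds derived from the root seed; the
# (condition, iteration) -> seed mapping is fixed by construction.
derive_seeds <- function(root_seed, n_conditions, n_iterations) {
  matrix(with_seed(root_seed,
                   sample.int(.Machine$integer.max - 1L,
                              n_conditions * n_iterations)),
         nrow = n_iterations, ncol = n_conditions)
}

#' Pooled relative noise level of measured curves
#'
#' Returns \code{100 * ||data - clean||_2 / ||clean||_2} pooled over all
#' curves of all samples: the fraction of total signal energy not explained
#' by the fitted clean curves, as a percentage.
#'
#' @param measurements list of \code{\link{dual_probe_measurement}}.
#' @param clean_fits matched list of \code{\link{dual_probe_measurement}}
#'   holding the fitted clean curves on the same grids (e.g. from
#'   \code{\link{fit_clean_curves}}).
#' @return Noise level in percent.
#' @export
estimate_noise_percent <- function(measurements, clean_fits) {
  stopifnot(length(measurements) == length(clean_fits),
            length(measurements) > 0)
  d2 <- 0
  c2 <- 0
  for (i in seq_along(measurements)) {
    m <- measurements[[i]]
    cl <- clean_fits[[i]]
    for (p in c("targeted", "untargeted")) {
      if (length(m[[p]]$values) != length(cl[[p]]$values)) {
        stop("clean fit ", i, " not aligned to its measurement",
             call. = FALSE)
      }
      d2 <- d2 + sum((m[[p]]$values - cl[[p]]$values)^2)
      c2 <- c2 + sum(cl[[p]]$values^2)
    }
  }
  if (c2 == 0) stop("clean signal is identically zero", call. = FALSE)
  100 * sqrt(d2 / c2)
}

#' Model-predicted curve of a fit
#'
#' Evaluates the fitted compartment model at given times: the basis of
#' unit-initial total curves times the fitted amplitudes.
#'
#' @param object a \code{"bp_fit"} from one of the model estimators (not
#'   \code{"Ratio"}).
#' @param times evaluation times (minutes); defaults to error if missing.
#' @param ... unused.
#' @return Numeric vector of predicted total concentrations (pM).
#' @export
predict.bp_fit <- function(object, times, ...) {
  if (object$estimator == "Ratio") {
    stop("the ratiometric estimator has no model curve", call. = FALSE)
  }
  r <- object$rates
  targeted <- !is.na(r$k3)
  variant <- if (object$estimator == "DPM-NS") "DPM-NS" else "DPM"
  rc <- rate_constants(F = r$F,
                       k3 = if (targeted) r$k3 else 0,
                       k4 = if (targeted) r$k4 else 0,
                       k5 = if (variant == "DPM-NS") r$k5 else 0,
                       k6 = if (variant == "DPM-NS") r$k6 else 0)
  probe <- if (targeted) "targeted" else "untargeted"
  B <- model_basis(rc, variant, probe, times)
  as.numeric(B %*% object$amplitudes[colnames(B)])
}

#' Fitted clean curves for a dual-probe measurement
#'
#' Runs the two-step DPM-NS fit on both curves and returns the model
#' predictions as a measurement object, for use as the clean reference in
#' \code{\link{estimate_noise_percent}}.
#'
#' @param measurement a \code{\link{dual_probe_measurement}}.
#' @param ... passed to \code{\link{fit_untargeted_dpmns}} /
#'   \code{\link{fit_targeted_dpmns}} (e.g. \code{k4_fixed}).
#' @return A \code{\link{dual_probe_measurement}} of fitted curves.
#' @export
fit_clean_curves <- function(measurement, ...) {
  stopifnot(inherits(measurement, "dual_probe_measurement"))
  tt <- measurement$targeted$times
  fu <- fit_untargeted_dpmns(measurement$untargeted)
  ft <- fit_targeted_dpmns(measurement$targeted, F = fu$rates$F,
                           k5 = fu$rates$k5, k6 = fu$rates$k6, ...)
  dual_probe_measurement(
    measurement$sample_id, measurement$tissue_label,
    targeted = concentration_curve("targeted", tt, predict(ft, tt)),
    untargeted = concentration_curve("untargeted", tt, predict(fu, tt)))
}

sweep_estimators <- c("Ratio", "DPM", "DPM-NS")

apply_estimators <- function(m, estimators, k4_fixed, opts) {
  vapply(estimators, function(est) {
    switch(est,
      # the reference can wash below the usable floor (no NS binding,
      # strong washout): such iterations yield NA rather than an error
      "Ratio" = tryCatch(bp_ratio(m)$bp, error = function(e) NA_real_),
      "DPM" = fit_dual_probe(m, "dpm", k4_fixed = k4_fixed, opts = opts)$bp,
      "DPM-NS" = fit_dual_probe(m, "dpmns", k4_fixed = k4_fixed,
                                opts = opts)$bp)
  }, numeric(1))
}

#' Nonspecific-binding sweep of estimator error
#'
#' For each nonspecific association rate in \code{config$k5_sweep},
#' simulates \code{n_iterations} noisy dual-probe datasets at the fixed BP
#' and applies the three estimators; tabulates the absolute BP error per
#' estimator. Reproducible: all randomness derives from \code{config$seed}.
#'
#' @param config a \code{\link{simulation_config}}.
#' @param estimators subset of \code{c("Ratio", "DPM", "DPM-NS")}.
#' @return An object of class \code{"ns_sweep"}: list with \code{estimates}
#'   (tidy data frame: k5, ns_ratio, estimator, iteration, estimate,
#'   abs_error) and \code{summary} (mean and s.d. of absolute error per
#'   ns_ratio x estimator, with \code{n_valid} counting iterations where
#'   the estimator was defined: the ratio is NA when the untargeted
#'   reference has washed below its usable floor).
#' @export
run_ns_sweep <- function(config = simulation_config(),
                         estimators = sweep_estimators) {
  stopifnot(inherits(config, "simulation_config"),
            length(config$k5_sweep) > 0)
  estimators <- match.arg(estimators, sweep_estimators, several.ok = TRUE)
  bp <- config$bp_fixed_for_sweep
  seeds <- derive_seeds(config$seed, length(config$k5_sweep),
                        config$n_iterations)
  opts <- solver_options()
  rows <- vector("list", length(config$k5_sweep))
  for (ci in seq_along(config$k5_sweep)) {
    k5 <- config$k5_sweep[ci]
    r <- rate_constants(F = config$F_washout, k3 = bp * config$k4,
                        k4 = config$k4, k5 = k5, k6 = config$k6)
    est <- t(vapply(seq_len(config$n_iterations), function(it) {
      m <- simulate_dual_probe(r, config$schedule, config$noise_percent,
                               seed = seeds[it, ci])
      apply_estimators(m, estimators, config$k4, opts)
    }, numeric(length(estimators))))
    rows[[ci]] <- data.frame(
      k5 = k5, ns_ratio = if (config$k6 > 0) k5 / config$k6 else NA_real_,
      estimator = rep(estimators, each = config$n_iterations),
      iteration = rep(seq_len(config$n_iterations), length(estimators)),
      estimate = as.vector(est))
  }
  estimates <- do.call(rbind, rows)
  estimates$abs_error <- abs(estimates$estimate - bp)
  agg <- stats::aggregate(abs_error ~ ns_ratio + estimator, estimates,
                          function(x) c(mean = mean(x, na.rm = TRUE),
                                        sd = stats::sd(x, na.rm = TRUE),
                                        n_valid = sum(!is.na(x))),
                          na.action = stats::na.pass)
  summary <- data.frame(ns_ratio = agg$ns_ratio, estimator = agg$estimator,
                        mean_abs_error = agg$abs_error[, "mean"],
                        sd_abs_error = agg$abs_error[, "sd"],
                        n_valid = as.integer(agg$abs_error[, "n_valid"]))
  summary <- summary[order(summary$estimator, summary$ns_ratio), ]
  rownames(summary) <- NULL
  structure(list(estimates = estimates, summary = summary,
                 bp_true = bp, config = config),
            class = "ns_sweep")
}

#' @export
print.ns_sweep <- function(x, ...) {
  cat(sprintf("Nonspecific-binding sweep at BP = %g (%d iterations):\n",
              x$bp_true, x$config$n_iterations))
  print(x$summary, digits = 3)
  invisible(x)
}

#' BP recovery distributions at tissue-like levels
#'
#' For each generating BP level, simulates \code{n_iterations} noisy
#' dual-probe datasets at the default nonspecific binding
#' (\code{k5_default}, \code{k6}) and estimates BP with the ratiometric and
#' DPM-NS estimators; returns the full estimate distributions with
#' summaries.
#'
#' @param config a \code{\link{simulation_config}}.
#' @param estimators subset of \code{c("Ratio", "DPM", "DPM-NS")}; default
#'   the two discriminating estimators.
#' @return An object of class \code{"bp_recovery"}: list with
#'   \code{estimates} (bp_true, estimator, iteration, estimate) and
#'   \code{summary} (mean, s.d., quartiles per level x estimator).
#' @export
run_recovery <- function(config = simulation_config(),
                         estimators = c("Ratio", "DPM-NS")) {
  stopifnot(inherits(config, "simulation_config"))
  estimators <- match.arg(estimators, sweep_estimators, several.ok = TRUE)
  seeds <- derive_seeds(config$seed, length(config$bp_levels),
                        config$n_iterations)
  opts <- solver_options()
  rows <- vector("list", length(config$bp_levels))
  for (ci in seq_along(config$bp_levels)) {
    bp <- config$bp_levels[ci]
    r <- rate_constants(F = config$F_washout, k3 = bp * config$k4,
                        k4 = config$k4, k5 = config$k5_default,
                        k6 = config$k6)
    est <- t(vapply(seq_len(config$n_iterations), function(it) {
      m <- simulate_dual_probe(r, config$schedule, config$noise_percent,
                               seed = seeds[it, ci])
      apply_estimators(m, estimators, config$k4, opts)
    }, numeric(length(estimators))))
    rows[[ci]] <- data.frame(
      bp_true = bp,
      estimator = rep(estimators, each = config$n_iterations),
      iteration = rep(seq_len(config$n_iterations), length(estimators)),
      estimate = as.vector(est))
  }
  estimates <- do.call(rbind, rows)
  agg <- stats::aggregate(estimate ~ bp_true + estimator, estimates,
                          function(x) c(mean = mean(x), sd = stats::sd(x),
                                        q1 = unname(stats::quantile(x, .25)),
                                        median = stats::median(x),
                                        q3 = unname(stats::quantile(x, .75))))
  summary <- cbind(agg[c("bp_true", "estimator")],
                   as.data.frame(agg$estimate))
  summary <- summary[order(summary$estimator, summary$bp_true), ]
  rownames(summary) <- NULL
  structure(list(estimates = estimates, summary = summary, config = config),
            class = "bp_recovery")
}

#' @export
print.bp_recovery <- function(x, ...) {
  cat(sprintf("BP recovery study (%d iterations per level):\n",
              x$config$n_iterations))
  print(x$summary, digits = 3)
  invisible(x)
}
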