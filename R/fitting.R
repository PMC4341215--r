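#' @title BP estimators for dual-probe rinse curves
#' @name fitting
#' @description
#' Two-step separable non-negative least-squares estimation of kinetic
#' parameters and binding potential (BP = k3/k4) from paired
#' targeted/untargeted rinse curves, following the sequential scheme: the
#' untargeted curve fixes the washout (and, for DPM-NS, nonspecific) rates,
#' which are then held fixed while the targeted curve is fit for k3 and k4.
NULL

# FitResult container ---------------------------------------------------

new_bp_fit <- function(estimator, rates, amplitudes, bp, residual_norm,
                       n_points, converged) {
  structure(list(estimator = estimator, rates = rates,
                 amplitudes = amplitudes, bp = bp,
                 residual_norm = residual_norm, n_points = n_points,
                 converged = converged),
            class = "bp_fit")
}

#' @export
print.bp_fit <- function(x, ...) {
  cat(sprintf("BP fit [%s]: BP = %.4g (residual %.4g pM over %d points%s)\n",
              x$estimator, x$bp, x$residual_norm, x$n_points,
              if (x$converged) "" else ", NOT converged"))
  r <- x$rates
  est <- !vapply(r, is.na, logical(1))
  if (any(est)) {
    cat("  rates (min^-1): ",
        paste(sprintf("%s = %.4g", names(r)[est], unlist(r[est])),
              collapse = ", "), "\n", sep = "")
  }
  invisible(x)
}

#' Convert a fit to a JSON record
#'
#' @param fit a \code{"bp_fit"} object.
#' @return A JSON string (single record).
#' @export
bp_fit_json <- function(fit) {
  stopifnot(inherits(fit, "bp_fit"))
  jsonlite::toJSON(unclass(fit), auto_unbox = TRUE, digits = NA,
                   na = "null", pretty = TRUE)
}

na_rates <- function(...) {
  r <- list(F = NA_real_, k3 = NA_real_, k4 = NA_real_,
            k5 = NA_real_, k6 = NA_real_)
  utils::modifyList(r, list(...))
}

# Exponential-basis columns: total concentration curves produced by a unit
# initial amount in each active compartment, with washout on. Exported
# model surface kept in R; the fit objectives use the compiled equivalent.
model_basis <- function(rates, variant, probe, times) {
  A <- build_generator(rates, variant, probe, washout_active = TRUE)
  act <- active_compartments(variant, probe)
  idx <- match(act, c("free", "bound", "ns"))
  Asub <- A[idx, idx, drop = FALSE]
  ed <- generator_eigen(Asub)
  if (!is.null(ed)) {
    u <- colSums(ed$vectors)                 # 1' V
    B <- exp(outer(times, ed$values)) %*% (u * ed$vinv)
  } else {
    B <- t(vapply(times, function(t)
      colSums(as.matrix(Matrix::expm(Asub * t))), numeric(length(idx))))
  }
  colnames(B) <- act
  B
}

default_lambda <- function(basis) {
  1e-4 * sum(basis^2) / ncol(basis)
}

kacz_lambda <- function(opts) {
  if (is.null(opts$tikhonov_lambda)) -1 else opts$tikhonov_lambda
}

# Multi-start Nelder-Mead over log-rates with linear amplitudes solved per
# candidate; `objective(par)` returns list(rss = ..., ...). Starts:
# n_starts values log-spaced over [0.01, 1] min^-1, every searched rate set
# to the start value; all starts are polished; ties in residual broken
# toward smaller BP when the candidate carries one.
separable_search <- function(n_par, objective, n_starts = 8L) {
  starts <- exp(seq(log(0.01), log(1), length.out = n_starts))
  best <- NULL
  obj_rss <- function(theta) {
    p <- exp(theta)
    if (any(p > 100)) return(1e12)
    objective(p)$rss
  }
  for (s in starts) {
    opt <- stats::optim(rep(log(s), n_par), obj_rss, method = "Nelder-Mead",
                        control = list(reltol = 1e-12, maxit = 1000))
    # Nelder-Mead can stall in narrow curved valleys; restarting the
    # simplex at its own solution recovers the lost progress
    for (restart in 1:2) {
      opt2 <- stats::optim(opt$par, obj_rss, method = "Nelder-Mead",
                           control = list(reltol = 1e-12, maxit = 1000))
      if (opt2$value < opt$value * (1 - 1e-9)) opt <- opt2 else break
    }
    cand <- objective(exp(opt$par))
    cand$par <- exp(opt$par)
    if (is.null(best) || cand$rss < best$rss * (1 - 1e-10) ||
        (abs(cand$rss - best$rss) <= 1e-10 * max(best$rss, 1e-300) &&
         !is.null(cand$bp) && !is.null(best$bp) && cand$bp < best$bp)) {
      best <- cand
    }
  }
  best
}

#' Ratiometric binding-potential estimate
#'
#' \code{BP_Ratio = (targeted - untargeted) / untargeted} at a single rinse
#' step, by default the final rinse. Under equilibrium-like conditions this
#' ratio approximates BP; it requires no model fit but is negatively biased
#' in the presence of nonspecific binding and can be negative under noise.
#'
#' @param measurement a \code{\link{dual_probe_measurement}}.
#' @param rinse_index 0-based measurement index (0 = pre-rinse); default is
#'   the final rinse.
#' @param epsilon smallest usable untargeted concentration (pM); values at
#'   or below it raise an error (unusable reference).
#' @return A \code{"bp_fit"} with estimator \code{"Ratio"}.
#' @export
bp_ratio <- function(measurement, rinse_index = NULL, epsilon = 1e-6) {
  stopifnot(inherits(measurement, "dual_probe_measurement"))
  n <- length(measurement$targeted$values)
  if (is.null(rinse_index)) rinse_index <- n - 1L
  if (rinse_index < 0 || rinse_index > n - 1L) {
    stop("rinse_index outside the curve", call. = FALSE)
  }
  i <- rinse_index + 1L
  u <- measurement$untargeted$values[i]
  if (u <= epsilon) {
    stop("untargeted concentration at rinse ", rinse_index,
         " is <= ", epsilon, " pM: unusable reference for the ratio",
         call. = FALSE)
  }
  tg <- measurement$targeted$values[i]
  new_bp_fit("Ratio", na_rates(), amplitudes = NULL, bp = (tg - u) / u,
             residual_norm = 0, n_points = 1L, converged = TRUE)
}

#' Fit the washout-only model to an untargeted curve
#'
#' Fits \code{A exp(-F t)} (free compartment with washout, no binding) by
#' profiling: for each candidate \code{F >= 0} the amplitude is the
#' non-negative least-squares solution in closed form; \code{F} is then
#' found by 1-D minimization of the profiled residual, with the
#' \code{F = 0} boundary preferred on ties (constant curves).
#'
#' @param curve an untargeted \code{\link{concentration_curve}} with at
#'   least 3 points.
#' @param F_max upper bound of the washout-rate search (min^-1).
#' @return A \code{"bp_fit"} with estimator \code{"DPM"}, the estimated
#'   \code{F} and the amplitude (no BP: \code{bp = NA}).
#' @export
fit_untargeted_dpm <- function(curve, F_max = 10) {
  stopifnot(inherits(curve, "concentration_curve"))
  if (curve$probe_label != "untargeted") {
    stop("curve must be labeled 'untargeted'", call. = FALSE)
  }
  y <- curve$values
  tt <- curve$times
  if (length(y) < 3L) stop("need at least 3 points", call. = FALSE)
  if (all(y == 0)) stop("degenerate input: all-zero curve", call. = FALSE)
  prof <- function(F) {
    e <- exp(-F * tt)
    a <- max(0, sum(y * e) / sum(e * e))
    list(rss = sum((y - a * e)^2), a = a)
  }
  opt <- stats::optimize(function(F) prof(F)$rss, c(0, F_max), tol = 1e-10)
  cand <- c(0, opt$minimum)
  rss <- vapply(cand, function(F) prof(F)$rss, numeric(1))
  F_hat <- cand[which(rss <= min(rss) * (1 + 1e-12))[1L]]
  p <- prof(F_hat)
  new_bp_fit("DPM", na_rates(F = F_hat), amplitudes = c(free = p$a),
             bp = NA_real_, residual_norm = sqrt(p$rss),
             n_points = length(y), converged = TRUE)
}

#' Fit the two-compartment dual-probe model to a targeted curve
#'
#' With the washout rate fixed from the untargeted fit, estimates the
#' specific binding rates \code{k3, k4 >= 0} of the free+bound model by a
#' multi-start Nelder-Mead search over log-rates; at each candidate the two
#' initial amplitudes are solved by non-negative least squares.
#' \code{BP = k3/k4}. If \code{k4} hits its lower floor the BP is reported
#' at the box constraint and the fit flagged non-converged.
#'
#' @param curve a targeted \code{\link{concentration_curve}}.
#' @param F_fixed washout rate (min^-1) from \code{\link{fit_untargeted_dpm}}.
#' @param k4_fixed optional known dissociation rate (min^-1). When given,
#'   only \code{k3} is searched (1-D) and \code{BP = k3/k4_fixed}; this is
#'   how the Monte-Carlo study fits simulated data, mirroring the use of a
#'   literature dissociation rate. \code{NULL} (default) estimates both.
#' @param k4_floor smallest admissible \code{k4} (min^-1) when \code{k4}
#'   is estimated.
#' @return A \code{"bp_fit"} with estimator \code{"DPM"}.
#' @export
fit_targeted_dpm <- function(curve, F_fixed, k4_fixed = NULL,
                             k4_floor = 1e-6) {
  stopifnot(inherits(curve, "concentration_curve"), F_fixed >= 0)
  y <- curve$values
  tt <- curve$times
  if (all(y == 0)) stop("degenerate input: all-zero curve", call. = FALSE)
  if (!is.null(k4_fixed)) {
    stopifnot(k4_fixed > 0)
    best <- k3_profile_search(function(k3)
      .cpp_obj_t_dpm(k3, k4_fixed, F_fixed, tt, y), k4_fixed)
    return(finalize_targeted_fit("DPM", best, F_fixed, NA_real_, NA_real_,
                                 c("free", "bound"), length(y), 0))
  }
  objective <- function(p) {
    o <- .cpp_obj_t_dpm(p[1L], p[2L], F_fixed, tt, y)
    o$bp <- p[1L] / p[2L]
    o
  }
  best <- separable_search(2L, objective)
  finalize_targeted_fit("DPM", best, F_fixed, NA_real_, NA_real_,
                        c("free", "bound"), length(y), k4_floor)
}

# 1-D profiled search over k3 with k4 known: golden-section on log k3 plus
# an explicit comparison against the k3 = 0 (no specific binding) limit.
k3_profile_search <- function(obj_fun, k4_fixed) {
  o <- stats::optimize(function(lk3) obj_fun(exp(lk3))$rss,
                       c(log(1e-8), log(100)), tol = 1e-12)
  k3_hat <- exp(o$minimum)
  best <- obj_fun(k3_hat)
  null_fit <- obj_fun(1e-12)   # numerically the no-specific-binding limit
  if (null_fit$rss <= best$rss) {
    best <- null_fit
    k3_hat <- 0
  }
  best$par <- c(k3_hat, k4_fixed)
  best$bp <- k3_hat / k4_fixed
  best
}

finalize_targeted_fit <- function(estimator, best, F_fixed, k5, k6,
                                  comp_names, n_points, k4_floor) {
  k3 <- best$par[1L]
  k4 <- best$par[2L]
  conv <- TRUE
  if (k4 < k4_floor) {
    k4 <- k4_floor
    conv <- FALSE
  }
  a <- stats::setNames(as.numeric(best$coef), comp_names)
  new_bp_fit(estimator,
             na_rates(F = F_fixed, k3 = k3, k4 = k4, k5 = k5, k6 = k6),
             amplitudes = a, bp = k3 / k4,
             residual_norm = sqrt(best$rss), n_points = n_points,
             converged = conv)
}

#' Fit the washout + nonspecific-binding model to an untargeted curve
#'
#' Estimates \code{F, k5, k6 >= 0} of the free+nonspecific two-compartment
#' system under washout by a multi-start Nelder-Mead search over log-rates
#' with the linear amplitude step solved per candidate.
#'
#' Two amplitude parameterizations are available. The default,
#' \code{"stain"}, anchors the rinse-phase initial state to the staining
#' kinetics: a unit of applied probe is propagated through the (known)
#' stain duration under the candidate \code{k5, k6} and only the overall
#' applied-concentration scale is solved linearly (ridge-regularized,
#' non-negative). This leaves 4 parameters for the 4 degrees of freedom of
#' a biexponential and makes the rates identifiable. \code{"free"} instead
#' treats both initial compartment amplitudes as free non-negative
#' coefficients of the biexponential basis, solved by
#' \code{\link{kaczmarz_tikhonov_solve}}; the rate triple is then only
#' identified up to the eigenvalue pair it produces, so fitted rates may
#' differ from generating ones while reproducing the curve.
#'
#' @param curve an untargeted \code{\link{concentration_curve}} with at
#'   least 5 points.
#' @param opts a \code{\link{solver_options}}; a \code{NULL}
#'   \code{tikhonov_lambda} defaults to \code{1e-4 * trace(B'B)/ncol(B)}.
#' @param amplitude_mode \code{"stain"} (default) or \code{"free"}.
#' @param stain_duration staining time (minutes) used by the
#'   \code{"stain"} anchor.
#' @return A \code{"bp_fit"} with estimator \code{"DPM-NS"} carrying
#'   \code{F}, \code{k5}, \code{k6}.
#' @export
fit_untargeted_dpmns <- function(curve, opts = solver_options(),
                                 amplitude_mode = c("stain", "free"),
                                 stain_duration = 10) {
  stopifnot(inherits(curve, "concentration_curve"))
  amplitude_mode <- match.arg(amplitude_mode)
  if (curve$probe_label != "untargeted") {
    stop("curve must be labeled 'untargeted'", call. = FALSE)
  }
  y <- curve$values
  tt <- curve$times
  if (length(y) < 5L) stop("need at least 5 points (3 rates + 2 amplitudes)",
                           call. = FALSE)
  if (all(y == 0)) stop("degenerate input: all-zero curve", call. = FALSE)
  objective <- if (amplitude_mode == "stain") {
    function(p) .cpp_obj_u_dpmns_stain(p[1L], p[2L], p[3L], tt, y,
                                       stain_duration, 0)
  } else {
    function(p) .cpp_obj_u_dpmns_free(p[1L], p[2L], p[3L], tt, y,
                                      kacz_lambda(opts), opts$max_sweeps,
                                      opts$tolerance, opts$seed)
  }
  best <- separable_search(3L, objective)
  a <- if (amplitude_mode == "stain") {
    stats::setNames(as.numeric(best$state), c("free", "ns"))
  } else {
    stats::setNames(as.numeric(best$coef), c("free", "ns"))
  }
  new_bp_fit("DPM-NS",
             na_rates(F = best$par[1L], k5 = best$par[2L], k6 = best$par[3L]),
             amplitudes = a, bp = NA_real_,
             residual_norm = sqrt(best$rss), n_points = length(y),
             converged = if (is.null(best$converged)) TRUE
                         else isTRUE(best$converged))
}

#' Fit the full three-compartment model to a targeted curve
#'
#' With \code{F}, \code{k5} and \code{k6} fixed from the untargeted DPM-NS
#' fit, estimates \code{k3, k4 >= 0}; \code{BP = k3/k4}. In the default
#' \code{"stain"} amplitude mode the initial rinse-phase state is anchored
#' to the staining kinetics under the candidate rates and only the overall
#' scale is solved linearly (the one-column Kaczmarz--Tikhonov solution),
#' which keeps BP identifiable. In \code{"free"} mode the three initial
#' amplitudes of the triexponential basis are free non-negative
#' coefficients solved by \code{\link{kaczmarz_tikhonov_solve}}; near-flat
#' residual directions then make the fitted BP strongly data-dependent
#' (documented limitation of that parameterization).
#'
#' @param curve a targeted \code{\link{concentration_curve}}.
#' @param F,k5,k6 rates (min^-1) fixed from
#'   \code{\link{fit_untargeted_dpmns}}.
#' @param opts a \code{\link{solver_options}}.
#' @param amplitude_mode \code{"stain"} (default) or \code{"free"}.
#' @param stain_duration staining time (minutes) for the \code{"stain"}
#'   anchor.
#' @param k4_fixed optional known dissociation rate (min^-1); when given
#'   only \code{k3} is searched. See \code{\link{fit_targeted_dpm}}.
#' @param k4_floor smallest admissible \code{k4} (min^-1) when \code{k4}
#'   is estimated.
#' @return A \code{"bp_fit"} with estimator \code{"DPM-NS"}.
#' @export
fit_targeted_dpmns <- function(curve, F, k5, k6, opts = solver_options(),
                               amplitude_mode = c("stain", "free"),
                               stain_duration = 10, k4_fixed = NULL,
                               k4_floor = 1e-6) {
  stopifnot(inherits(curve, "concentration_curve"),
            F >= 0, k5 >= 0, k6 >= 0)
  amplitude_mode <- match.arg(amplitude_mode)
  y <- curve$values
  tt <- curve$times
  if (all(y == 0)) stop("degenerate input: all-zero curve", call. = FALSE)
  objective <- if (amplitude_mode == "stain") {
    function(p) {
      o <- .cpp_obj_t_dpmns_stain(p[1L], p[2L], F, k5, k6, tt, y,
                                  stain_duration, 0)
      o$coef <- o$state
      o$bp <- p[1L] / p[2L]
      o
    }
  } else {
    function(p) {
      o <- .cpp_obj_t_dpmns(p[1L], p[2L], F, k5, k6, tt, y,
                            kacz_lambda(opts), opts$max_sweeps,
                            opts$tolerance, opts$seed)
      o$bp <- p[1L] / p[2L]
      o
    }
  }
  if (!is.null(k4_fixed)) {
    stopifnot(k4_fixed > 0)
    best <- k3_profile_search(function(k3) objective(c(k3, k4_fixed)),
                              k4_fixed)
    return(finalize_targeted_fit("DPM-NS", best, F, k5, k6,
                                 c("free", "bound", "ns"), length(y), 0))
  }
  best <- separable_search(2L, objective)
  finalize_targeted_fit("DPM-NS", best, F, k5, k6,
                        c("free", "bound", "ns"), length(y), k4_floor)
}

#' Two-step BP estimation for one dual-probe measurement
#'
#' Applies one of the three estimators end to end: \code{"ratio"} is the
#' single-time-point ratiometric estimate; \code{"dpm"} fits the untargeted
#' curve for the washout rate and then the targeted curve for
#' \code{k3, k4}; \code{"dpmns"} fits the untargeted curve for \code{F, k5,
#' k6} and then the targeted curve for \code{k3, k4} with those rates fixed.
#'
#' @param measurement a \code{\link{dual_probe_measurement}}.
#' @param estimator \code{"ratio"}, \code{"dpm"} or \code{"dpmns"}.
#' @param rinse_index passed to \code{\link{bp_ratio}} (ratio only).
#' @param opts a \code{\link{solver_options}} (DPM-NS only).
#' @param amplitude_mode amplitude parameterization of the DPM-NS fits,
#'   \code{"stain"} (anchored, default) or \code{"free"}.
#' @param stain_duration minutes of staining, used by the DPM-NS
#'   stain-phase amplitude anchor.
#' @param k4_fixed optional known dissociation rate passed to the targeted
#'   fit (see \code{\link{fit_targeted_dpm}}).
#' @return A \code{"bp_fit"} for the targeted curve.
#' @examples
#' r <- rate_constants(F = 0.2, k3 = 0.1, k4 = 0.1, k5 = 0.16, k6 = 0.06)
#' m <- simulate_dual_probe(r, noise_percent = 0, seed = 1)
#' fit_dual_probe(m, "dpmns")$bp
#' @export
fit_dual_probe <- function(measurement, estimator = c("dpmns", "dpm", "ratio"),
                           rinse_index = NULL, opts = solver_options(),
                           amplitude_mode = c("stain", "free"),
                           stain_duration = 10, k4_fixed = NULL) {
  stopifnot(inherits(measurement, "dual_probe_measurement"))
  estimator <- match.arg(estimator)
  amplitude_mode <- match.arg(amplitude_mode)
  switch(estimator,
    ratio = bp_ratio(measurement, rinse_index),
    dpm = {
      fu <- fit_untargeted_dpm(measurement$untargeted)
      fit_targeted_dpm(measurement$targeted, F_fixed = fu$rates$F,
                       k4_fixed = k4_fixed)
    },
    dpmns = {
      fu <- fit_untargeted_dpmns(measurement$untargeted, opts,
                                 amplitude_mode = amplitude_mode,
                                 stain_duration = stain_duration)
      fit_targeted_dpmns(measurement$targeted, F = fu$rates$F,
                         k5 = fu$rates$k5, k6 = fu$rates$k6, opts = opts,
                         amplitude_mode = amplitude_mode,
                         stain_duration = stain_duration,
                         k4_fixed = k4_fixed)
    })
}
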