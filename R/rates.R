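#' Kinetic rate constants for a dual-probe rinse experiment
#'
#' Bundles the five first-order rate constants of the rinse-kinetics
#' compartment model: the rinse washout rate \code{F} acting on free probe,
#' the specific binding exchange rates \code{k3} (association) and \code{k4}
#' (dissociation), and the nonspecific exchange rates \code{k5} and
#' \code{k6}. The binding potential is \code{BP = k3/k4}, the equilibrium
#' ratio of specifically bound to free probe.
#'
#' @param F rinse washout rate of the free compartment (min^-1).
#' @param k3 specific association rate (min^-1).
#' @param k4 specific dissociation rate (min^-1). \code{BP} is only defined
#'   when \code{k4 > 0}.
#' @param k5 nonspecific association rate (min^-1).
#' @param k6 nonspecific dissociation rate (min^-1).
#' @return An object of class \code{"rate_constants"}: a named list with
#'   fields \code{F}, \code{k3}, \code{k4}, \code{k5}, \code{k6}.
#' @examples
#' rate_constants(F = 0.2, k3 = 0.1, k4 = 0.1, k5 = 0.16, k6 = 0.06)
#' @export
rate_constants <- function(F = 0, k3 = 0, k4 = 0, k5 = 0, k6 = 0) {
  r <- list(F = F, k3 = k3, k4 = k4, k5 = k5, k6 = k6)
  for (nm in names(r)) {
    v <- r[[nm]]
    if (!is.numeric(v) || length(v) != 1L || is.na(v) || v < 0) {
      stop("rate constant '", nm, "' must be a single non-negative number",
           call. = FALSE)
    }
  }
  structure(r, class = "rate_constants")
}

#' @export
print.rate_constants <- function(x, ...) {
  cat("Rate constants (min^-1):\n")
  cat(sprintf("  F = %g, k3 = %g, k4 = %g, k5 = %g, k6 = %g\n",
              x$F, x$k3, x$k4, x$k5, x$k6))
  if (x$k4 > 0) cat(sprintf("  BP = k3/k4 = %g\n", x$k3 / x$k4))
  invisible(x)
}

#' Binding potential implied by a set of rate constants
#'
#' @param rates a \code{\link{rate_constants}} object with \code{k4 > 0}.
#' @return \code{k3/k4}.
#' @export
binding_potential <- function(rates) {
  stopifnot(inherits(rates, "rate_constants"))
  if (rates$k4 <= 0) stop("BP = k3/k4 undefined: k4 must be > 0", call. = FALSE)
  rates$k3 / rates$k4
}

#' Measurement schedule of a stain-and-rinse acquisition
#'
#' Describes when probe concentrations are measured: the tissue is stained
#' for \code{stain_duration} minutes, then measured before (optionally) and
#' after each of \code{n_rinses} saline rinses performed at regular
#' \code{rinse_interval} spacing. Measurement \code{i} (0-based, 0 = the
#' pre-rinse reading) is taken at \code{t = i * rinse_interval} minutes
#' after the end of staining.
#'
#' @param stain_duration staining time in minutes (default 10).
#' @param rinse_interval minutes between successive measurements
#'   (default 0.5, i.e. ~30 s rinse cycles).
#' @param n_rinses number of rinse steps (default 10).
#' @param include_pre_rinse include the measurement taken after staining but
#'   before the first rinse (default \code{TRUE}).
#' @return An object of class \code{"acquisition_schedule"}.
#' @export
acquisition_schedule <- function(stain_duration = 10, rinse_interval = 0.5,
                                 n_rinses = 10, include_pre_rinse = TRUE) {
  stopifnot(is.numeric(stain_duration), stain_duration > 0,
            is.numeric(rinse_interval), rinse_interval > 0,
            is.numeric(n_rinses), n_rinses >= 2,
            is.logical(include_pre_rinse))
  structure(list(stain_duration = stain_duration,
                 rinse_interval = rinse_interval,
                 n_rinses = as.integer(n_rinses),
                 include_pre_rinse = include_pre_rinse),
            class = "acquisition_schedule")
}

#' Measurement times of a schedule
#'
#' @param schedule an \code{\link{acquisition_schedule}}.
#' @return Numeric vector of measurement times in minutes since the first
#'   (pre-rinse) time point; length \code{n_rinses + include_pre_rinse}.
#' @export
schedule_times <- function(schedule) {
  stopifnot(inherits(schedule, "acquisition_schedule"))
  first <- if (schedule$include_pre_rinse) 0L else 1L
  seq(first, schedule$n_rinses) * schedule$rinse_interval
}

#' Single-time-point concentration curve of one probe
#'
#' @param probe_label \code{"targeted"} or \code{"untargeted"}.
#' @param times minutes since the first measurement, strictly increasing.
#' @param values total probe concentration (pM) at each time.
#' @return An object of class \code{"concentration_curve"}.
#' @export
concentration_curve <- function(probe_label, times, values) {
  probe_label <- match.arg(probe_label, c("targeted", "untargeted"))
  stopifnot(is.numeric(times), is.numeric(values),
            length(times) == length(values))
  if (length(times) && any(diff(times) <= 0)) {
    stop("curve times must be strictly increasing", call. = FALSE)
  }
  structure(list(probe_label = probe_label,
                 times = as.numeric(times),
                 values = as.numeric(values)),
            class = "concentration_curve")
}

#' Paired targeted/untargeted curves for one tissue sample
#'
#' @param sample_id sample identifier.
#' @param tissue_label tissue group label (e.g. \code{"healthy"},
#'   \code{"U251"}, \code{"A431"}).
#' @param targeted,untargeted \code{\link{concentration_curve}} objects on
#'   a shared time grid with correct, distinct probe labels.
#' @return An object of class \code{"dual_probe_measurement"}.
#' @export
dual_probe_measurement <- function(sample_id, tissue_label, targeted, untargeted) {
  stopifnot(inherits(targeted, "concentration_curve"),
            inherits(untargeted, "concentration_curve"))
  if (targeted$probe_label != "targeted" ||
      untargeted$probe_label != "untargeted") {
    stop("curves must be labeled 'targeted' and 'untargeted' respectively",
         call. = FALSE)
  }
  if (!isTRUE(all.equal(targeted$times, untargeted$times))) {
    stop("targeted and untargeted curves must share identical times",
         call. = FALSE)
  }
  structure(list(sample_id = as.character(sample_id),
                 tissue_label = as.character(tissue_label),
                 targeted = targeted, untargeted = untargeted),
            class = "dual_probe_measurement")
}

#' @export
print.dual_probe_measurement <- function(x, ...) {
  cat(sprintf("Dual-probe measurement '%s' (%s): %d time points, %.3g-%.3g pM\n",
              x$sample_id, x$tissue_label, length(x$targeted$times),
              min(c(x$targeted$values, x$untargeted$values)),
              max(c(x$targeted$values, x$untargeted$values))))
  invisible(x)
}
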