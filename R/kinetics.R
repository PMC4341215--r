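#' Generator matrix of the rinse-kinetics compartment model
#'
#' Builds the linear ODE generator \code{A} such that \code{dC/dt = A C}
#' over the compartment vector \code{C = (free, bound, ns)}: free probe
#' exchanges with the specifically bound compartment at rates
#' \code{k3}/\code{k4} and with the nonspecific compartment at
#' \code{k5}/\code{k6}; during rinsing, free probe is additionally cleared
#' at the washout rate \code{F}. The \code{"DPM"} variant drops the
#' nonspecific compartment (its row and column are zero); an
#' \code{"untargeted"} probe has no specific binding (\code{k3 = k4 = 0} by
#' construction).
#'
#' @param rates a \code{\link{rate_constants}} object.
#' @param variant \code{"DPM-NS"} (three compartments) or \code{"DPM"}
#'   (no nonspecific compartment).
#' @param probe \code{"targeted"} or \code{"untargeted"}.
#' @param washout_active logical; apply the \code{-F} clearance to the free
#'   compartment (TRUE during the rinse phase, FALSE during staining).
#' @return A 3x3 matrix with rows/columns named \code{free}, \code{bound},
#'   \code{ns}. Binding exchange conserves total probe: excluding the
#'   washout term, every column sums to zero.
#' @export
build_generator <- function(rates, variant = c("DPM-NS", "DPM"),
                            probe = c("targeted", "untargeted"),
                            washout_active = TRUE) {
  stopifnot(inherits(rates, "rate_constants"))
  variant <- match.arg(variant)
  probe <- match.arg(probe)
  k3 <- if (probe == "untargeted") 0 else rates$k3
  k4 <- if (probe == "untargeted") 0 else rates$k4
  k5 <- if (variant == "DPM") 0 else rates$k5
  k6 <- if (variant == "DPM") 0 else rates$k6
  Fw <- if (washout_active) rates$F else 0
  A <- matrix(0, 3, 3, dimnames = list(c("free", "bound", "ns"),
                                       c("free", "bound", "ns")))
  A["free", "free"]  <- -(Fw + k3 + k5)
  A["free", "bound"] <- k4
  A["free", "ns"]    <- k6
  A["bound", "free"] <- k3
  A["bound", "bound"] <- -k4
  A["ns", "free"]    <- k5
  A["ns", "ns"]      <- -k6
  A
}

# Compartments that can carry probe for a given model variant and probe type.
active_compartments <- function(variant, probe) {
  act <- c(free = TRUE,
           bound = (probe == "targeted"),
           ns = (variant == "DPM-NS"))
  names(act)[act]
}

# Eigen-decomposition of the generator with a scaling-and-squaring fallback.
# Returns list(values, vectors, vinv) or NULL when near-defective (then
# callers evaluate exp(A t) directly via Matrix::expm).
generator_eigen <- function(A, gap_tol = 1e-10) {
  e <- eigen(A)
  if (max(abs(Im(e$values))) > 1e-9 * max(1, max(abs(e$values)))) {
    return(NULL)
  }
  vals <- Re(e$values)
  # near-degenerate eigenvalues can make V ill-conditioned (defective limit)
  if (min(dist(vals)) < gap_tol) return(NULL)
  V <- Re(e$vectors)
  if (rcond(V) < 1e-12) return(NULL)
  list(values = vals, vectors = V, vinv = solve(V))
}

# exp(A t) %*% c0 for a vector of times; rows = times, cols = compartments.
propagate_state <- function(A, c0, times) {
  ed <- generator_eigen(A)
  if (!is.null(ed)) {
    # c(t) = V exp(L t) V^-1 c0
    w <- as.vector(ed$vinv %*% c0)
    E <- exp(outer(times, ed$values))          # n_times x 3
    out <- E %*% (t(ed$vectors) * w)           # == t(V %*% (w * exp(L t)))
  } else {
    out <- t(vapply(times, function(t)
      as.vector(Matrix::expm(A * t) %*% c0), numeric(3)))
  }
  colnames(out) <- c("free", "bound", "ns")
  out
}

#' Solve the compartment system at given times
#'
#' Exact solution of the linear system \code{dC/dt = A C} from an initial
#' compartment state, by eigen-decomposition of the generator (with a
#' scaling-and-squaring matrix exponential fallback for near-degenerate
#' spectra).
#'
#' @param initial numeric vector \code{c(free, bound, ns)} in pM.
#' @param rates a \code{\link{rate_constants}} object.
#' @param times non-negative, increasing times (minutes).
#' @inheritParams build_generator
#' @return A matrix with one row per time and columns \code{free},
#'   \code{bound}, \code{ns}, plus attribute \code{"total"} holding the
#'   measured totals (row sums).
#' @export
solve_compartments <- function(initial, rates, times,
                               variant = c("DPM-NS", "DPM"),
                               probe = c("targeted", "untargeted"),
                               washout_active = TRUE) {
  stopifnot(is.numeric(initial), length(initial) == 3L)
  if (any(times < 0)) stop("times must be non-negative", call. = FALSE)
  if (is.unsorted(times, strictly = FALSE)) {
    stop("times must be increasing", call. = FALSE)
  }
  A <- build_generator(rates, variant, probe, washout_active)
  out <- propagate_state(A, initial, times)
  attr(out, "total") <- rowSums(out)
  out
}

#' Compartment state at the end of the staining phase
#'
#' Solves the system without washout from the initial state
#' \code{(applied_concentration, 0, 0)} for \code{stain_duration} minutes.
#' Total probe is conserved during staining (no clearance), so the total at
#' the end equals the applied concentration.
#'
#' @param applied_concentration applied probe concentration (pM), > 0.
#' @param rates a \code{\link{rate_constants}} object.
#' @param stain_duration staining time (minutes).
#' @inheritParams build_generator
#' @return Named numeric vector \code{c(free, bound, ns)} in pM.
#' @export
simulate_stain_phase <- function(applied_concentration, rates,
                                 stain_duration = 10,
                                 variant = c("DPM-NS", "DPM"),
                                 probe = c("targeted", "untargeted")) {
  stopifnot(applied_concentration > 0)
  st <- solve_compartments(c(applied_concentration, 0, 0), rates,
                           c(0, stain_duration), variant, probe,
                           washout_active = FALSE)
  stats::setNames(st[2L, ], c("free", "bound", "ns"))
}

# Evaluate code with a locally-set RNG state, restoring the caller's state.
with_seed <- function(seed, code) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

# Gaussian noise with sigma = (noise_percent/100) * RMS(clean), per point.
add_curve_noise <- function(clean, noise_percent) {
  if (noise_percent == 0) return(clean)
  sigma <- (noise_percent / 100) * sqrt(mean(clean^2))
  clean + stats::rnorm(length(clean), 0, sigma)
}

#' Simulate a paired targeted/untargeted rinse experiment
#'
#' Generates the clean targeted and untargeted total-concentration curves
#' for one tissue sample: both probes are stained for
#' \code{stain_duration} minutes from the same applied concentration
#' (no washout), then rinsed with washout active and measured on the
#' schedule's time grid. The untargeted probe shares \code{F}, \code{k5}
#' and \code{k6} with the targeted probe and has \code{k3 = k4 = 0}
#' (ideal isotype control). Gaussian noise with standard deviation
#' \code{(noise_percent/100) * RMS(clean curve)} is added independently per
#' point and per curve; negative noisy values are retained.
#'
#' @param rates_targeted \code{\link{rate_constants}} for the targeted probe.
#' @param schedule an \code{\link{acquisition_schedule}}.
#' @param noise_percent noise level as a percentage of the clean curve RMS
#'   (default 0.48).
#' @param seed integer seed; identical seeds give identical output. The
#'   caller's RNG state is untouched.
#' @param variant kinetic model used for generation (default
#'   \code{"DPM-NS"}).
#' @param applied_concentration staining concentration of each probe (pM,
#'   default 150).
#' @param sample_id,tissue_label identifiers carried into the result.
#' @return A \code{\link{dual_probe_measurement}}.
#' @examples
#' r <- rate_constants(F = 0.2, k3 = 0.1, k4 = 0.1, k5 = 0.16, k6 = 0.06)
#' m <- simulate_dual_probe(r, acquisition_schedule(), seed = 1)
#' @export
simulate_dual_probe <- function(rates_targeted, schedule = acquisition_schedule(),
                                noise_percent = 0.48, seed = 1L,
                                variant = c("DPM-NS", "DPM"),
                                applied_concentration = 150,
                                sample_id = "sim", tissue_label = "simulated") {
  stopifnot(inherits(rates_targeted, "rate_constants"), noise_percent >= 0)
  variant <- match.arg(variant)
  times <- schedule_times(schedule)
  clean <- lapply(c("targeted", "untargeted"), function(probe) {
    s0 <- simulate_stain_phase(applied_concentration, rates_targeted,
                               schedule$stain_duration, variant, probe)
    st <- solve_compartments(s0, rates_targeted, times, variant, probe,
                             washout_active = TRUE)
    attr(st, "total")
  })
  noisy <- with_seed(seed, lapply(clean, add_curve_noise, noise_percent))
  dual_probe_measurement(
    sample_id, tissue_label,
    targeted = concentration_curve("targeted", times, noisy[[1L]]),
    untargeted = concentration_curve("untargeted", times, noisy[[2L]]))
}
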