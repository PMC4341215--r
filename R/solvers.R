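#' Options for the randomized column Kaczmarz--Tikhonov solver
#'
#' @param tikhonov_lambda ridge penalty weight on the amplitude
#'   coefficients (>= 0), or \code{NULL} to let the fitting routines use
#'   their default \code{1e-4 * trace(B'B)/ncol(B)}.
#' @param max_sweeps maximum number of full column sweeps.
#' @param tolerance relative-change stopping threshold per sweep.
#' @param seed integer seed for the randomized column order.
#' @return An object of class \code{"solver_options"}.
#' @export
solver_options <- function(tikhonov_lambda = NULL, max_sweeps = 500L,
                           tolerance = 1e-12, seed = 17L) {
  if (!is.null(tikhonov_lambda)) stopifnot(tikhonov_lambda >= 0)
  stopifnot(max_sweeps >= 1, tolerance > 0)
  structure(list(tikhonov_lambda = tikhonov_lambda,
                 max_sweeps = as.integer(max_sweeps),
                 tolerance = tolerance, seed = as.integer(seed)),
            class = "solver_options")
}

#' Randomized column Kaczmarz solver with Tikhonov regularization
#'
#' Approximately minimizes \code{||B c - y||^2 + lambda ||c||^2} by
#' column-action (exact coordinate) updates visited in a randomized order
#' each sweep; with \code{nonneg = TRUE} each update is projected onto
#' \code{c_j >= 0}, which solves the non-negatively constrained ridge
#' problem. Deterministic under a fixed \code{opts$seed}; for
#' \code{nonneg = FALSE} the iterates converge to the closed-form solution
#' \code{(B'B + lambda I)^-1 B'y}.
#'
#' @param basis numeric matrix (time points x components).
#' @param observations numeric vector, \code{length == nrow(basis)}.
#' @param opts a \code{\link{solver_options}}; \code{tikhonov_lambda} must
#'   be set (use 0 for no regularization).
#' @param nonneg constrain coefficients to be non-negative.
#' @return Numeric coefficient vector with attributes \code{"converged"}
#'   (logical), \code{"sweeps"} and \code{"residual_norm"}.
#' @examples
#' B <- cbind(exp(-0.2 * 0:10), exp(-0.05 * 0:10))
#' y <- B %*% c(2, 1)
#' kaczmarz_tikhonov_solve(B, y, solver_options(tikhonov_lambda = 0))
#' @export
kaczmarz_tikhonov_solve <- function(basis, observations,
                                    opts = solver_options(tikhonov_lambda = 0),
                                    nonneg = FALSE) {
  basis <- as.matrix(basis)
  y <- as.numeric(observations)
  if (nrow(basis) != length(y)) {
    stop("basis and observations are not conformable", call. = FALSE)
  }
  lam <- opts$tikhonov_lambda
  if (is.null(lam)) stop("tikhonov_lambda must be set", call. = FALSE)
  res <- .cpp_kaczmarz(basis, y, lam, opts$max_sweeps, opts$tolerance,
                       opts$seed, nonneg)
  structure(as.numeric(res$coef), converged = res$converged,
            sweeps = res$sweeps, residual_norm = res$residual_norm)
}

# Non-negative least squares on a small dense system (Lawson-Hanson via
# pracma). Returns coefficients with residual_norm attribute.
nnls_solve <- function(basis, y) {
  basis <- as.matrix(basis)
  fit <- pracma::lsqnonneg(basis, as.numeric(y))
  cc <- fit$x
  structure(cc, converged = TRUE,
            residual_norm = sqrt(sum((y - basis %*% cc)^2)))
}
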