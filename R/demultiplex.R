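#' Raman-style channelized spectrum
#'
#' @param channels wavenumber grid (cm^-1), strictly increasing, >= 16
#'   channels.
#' @param intensities detector counts per channel.
#' @return An object of class \code{"raman_spectrum"}.
#' @export
raman_spectrum <- function(channels, intensities) {
  stopifnot(is.numeric(channels), is.numeric(intensities),
            length(channels) == length(intensities))
  if (length(channels) < 16L) {
    stop("a spectrum needs at least 16 channels", call. = FALSE)
  }
  if (any(diff(channels) <= 0)) {
    stop("channels must be strictly increasing", call. = FALSE)
  }
  structure(list(channels = as.numeric(channels),
                 intensities = as.numeric(intensities)),
            class = "raman_spectrum")
}

#' Default wavenumber grid for synthetic spectra
#'
#' @param n number of channels (default 400).
#' @param from,to grid range in cm^-1 (default 600-1800).
#' @return Numeric vector of channel positions.
#' @export
default_channels <- function(n = 400L, from = 600, to = 1800) {
  seq(from, to, length.out = n)
}

#' Synthesize a fingerprint reference spectrum
#'
#' Renders a sum of Lorentzian lines on a channel grid, emulating the
#' narrow fingerprint peaks of spectrally distinct nanoparticle flavors.
#' Deterministic.
#'
#' @param peaks list of \code{c(center, width, height)} triples (cm^-1,
#'   cm^-1 FWHM, arbitrary height), or a 3-column matrix.
#' @param channels wavenumber grid.
#' @return A \code{\link{raman_spectrum}}. A peak centered outside the
#'   grid raises a warning but is still rendered.
#' @examples
#' s <- synth_reference(list(c(1000, 12, 1), c(1450, 18, 0.6)))
#' @export
synth_reference <- function(peaks, channels = default_channels()) {
  if (is.matrix(peaks)) peaks <- asplit(peaks, 1L)
  y <- numeric(length(channels))
  for (p in peaks) {
    stopifnot(length(p) == 3L)
    ctr <- p[[1L]]
    w <- p[[2L]]
    h <- p[[3L]]
    if (w <= 0) stop("peak width must be > 0", call. = FALSE)
    if (ctr < min(channels) || ctr > max(channels)) {
      warning("peak center ", ctr, " cm^-1 lies outside the channel range",
              call. = FALSE)
    }
    y <- y + h / (1 + ((channels - ctr) / (w / 2))^2)
  }
  raman_spectrum(channels, y)
}

#' Reference library of flavor spectra plus tissue background
#'
#' @param flavor_spectra named list of \code{\link{raman_spectrum}}
#'   objects (e.g. targeted and untargeted flavors).
#' @param background \code{\link{raman_spectrum}} of unstained tissue on
#'   the same grid.
#' @return An object of class \code{"reference_library"}. Construction
#'   fails if the grids differ or the flavor spectra are collinear
#'   (condition number of the reference matrix > 1e8).
#' @export
reference_library <- function(flavor_spectra, background) {
  stopifnot(is.list(flavor_spectra), length(flavor_spectra) >= 1,
            !is.null(names(flavor_spectra)),
            all(nzchar(names(flavor_spectra))),
            inherits(background, "raman_spectrum"))
  grid <- background$channels
  for (nm in names(flavor_spectra)) {
    s <- flavor_spectra[[nm]]
    stopifnot(inherits(s, "raman_spectrum"))
    if (!isTRUE(all.equal(s$channels, grid))) {
      stop("flavor '", nm, "' is not on the background channel grid",
           call. = FALSE)
    }
  }
  M <- vapply(flavor_spectra, `[[`, numeric(length(grid)), "intensities")
  if (length(flavor_spectra) > 1L) {
    kap <- kappa(M, exact = TRUE)
    if (!is.finite(kap) || kap > 1e8) {
      cors <- stats::cor(M)
      diag(cors) <- 0
      worst <- which(abs(cors) == max(abs(cors)), arr.ind = TRUE)[1L, ]
      stop("flavor spectra are collinear (condition number ",
           format(kap, digits = 3), "); most collinear pair: '",
           colnames(M)[worst[1L]], "' and '", colnames(M)[worst[2L]], "'",
           call. = FALSE)
    }
  }
  structure(list(flavor_spectra = flavor_spectra, background = background,
                 channels = grid),
            class = "reference_library")
}

#' Direct classical least squares (DCLS) spectral unmixing
#'
#' Decomposes a measured spectrum as a weighted sum of the library's
#' flavor reference spectra plus the tissue background,
#' \code{spectrum ~ sum_i w_i ref_i + w_b background}, by (optionally
#' non-negative) least squares. The background can instead be subtracted
#' before unmixing (\code{background = "subtract"}).
#'
#' @param spectrum a \code{\link{raman_spectrum}} on the library grid.
#' @param library a \code{\link{reference_library}}.
#' @param nonneg constrain the weights to be non-negative (default TRUE).
#' @param background \code{"cofit"} (default; background enters as an
#'   extra component with a free weight) or \code{"subtract"} (background
#'   subtracted first, then flavors fit alone).
#' @param baseline_order 0 (default, none), 1 or 2: add polynomial
#'   baseline columns to the design.
#' @return List with \code{weights} (named, per flavor),
#'   \code{background_weight}, \code{baseline} (coefficients or NULL),
#'   \code{residual_norm} and \code{fitted}.
#' @examples
#' ch <- default_channels()
#' lib <- reference_library(
#'   list(S420 = synth_reference(list(c(950, 10, 1)), ch),
#'        S440 = synth_reference(list(c(1550, 10, 1)), ch)),
#'   background = synth_reference(list(c(1200, 300, 0.3)), ch))
#' mix <- raman_spectrum(ch, 2 * lib$flavor_spectra$S420$intensities +
#'                           0.5 * lib$flavor_spectra$S440$intensities +
#'                           lib$background$intensities)
#' dcls_unmix(mix, lib)$weights
#' @export
dcls_unmix <- function(spectrum, library, nonneg = TRUE,
                       background = c("cofit", "subtract"),
                       baseline_order = 0L) {
  stopifnot(inherits(spectrum, "raman_spectrum"),
            inherits(library, "reference_library"))
  background <- match.arg(background)
  if (!isTRUE(all.equal(spectrum$channels, library$channels))) {
    stop("spectrum is not on the library channel grid", call. = FALSE)
  }
  y <- spectrum$intensities
  flavors <- names(library$flavor_spectra)
  M <- vapply(library$flavor_spectra, `[[`, numeric(length(y)),
              "intensities")
  cols <- flavors
  if (background == "cofit") {
    M <- cbind(M, background = library$background$intensities)
    cols <- c(flavors, ".background")
  } else {
    y <- y - library$background$intensities
  }
  if (baseline_order > 0L) {
    x <- seq(-1, 1, length.out = length(y))
    for (d in seq_len(baseline_order)) {
      M <- cbind(M, x^d)
      cols <- c(cols, paste0(".baseline", d))
    }
  }
  colnames(M) <- cols
  if (nonneg) {
    w <- as.numeric(nnls_solve(M, y))
  } else {
    w <- as.numeric(qr.coef(qr(M), y))
  }
  names(w) <- cols
  fitted <- as.numeric(M %*% w)
  base_cols <- grep("^\\.baseline", cols)
  list(weights = w[flavors],
       background_weight = if (background == "cofit") w[[".background"]]
                           else NA_real_,
       baseline = if (length(base_cols)) w[base_cols] else NULL,
       residual_norm = sqrt(sum((y - fitted)^2)),
       fitted = fitted)
}

#' Calibrate demultiplexed weights to molar concentrations
#'
#' Converts per-flavor unmixing weights into concentrations using a stock
#' measurement of known concentration:
#' \code{concentration_i = weight_i * stock_concentration / stock_weight_i}.
#'
#' @param weights named numeric weights from \code{\link{dcls_unmix}}.
#' @param stock_weights weights obtained from the calibration stock
#'   droplet, same names; all > 0.
#' @param stock_concentration concentration of each flavor in the stock
#'   (pM, default 150: the equimolar staining mixture).
#' @return Named vector of concentrations (pM).
#' @export
calibrate <- function(weights, stock_weights, stock_concentration = 150) {
  stopifnot(length(weights) == length(stock_weights),
            stock_concentration > 0)
  if (any(stock_weights <= 0)) {
    stop("calibration error: zero or negative stock weight", call. = FALSE)
  }
  if (!is.null(names(weights)) && !is.null(names(stock_weights))) {
    stock_weights <- stock_weights[names(weights)]
  }
  weights * (stock_concentration / stock_weights)
}
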