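#' Uniform wavenumber grid
#'
#' Defines the shared spectral axis on which all spectra, basis libraries and
#' models in the package operate. The default covers the biological
#' fingerprint region (600--1800 cm^-1) sampled at 582 points, the input
#' length the CNN expects.
#'
#' @param start,end grid limits in cm^-1 (`end > start`).
#' @param n_points number of equally spaced samples (default 582).
#' @return an object of class `wavenumber_grid` with elements `start`, `end`,
#'   `n_points` and the numeric vector `wavenumbers`.
#' @export
#' @examples
#' g <- wavenumber_grid()
#' length(g$wavenumbers)
wavenumber_grid <- function(start = 600, end = 1800, n_points = 582L) {
  if (!is.numeric(start) || !is.numeric(end) || end <= start) {
    stop_config("end", "must exceed 'start'")
  }
  n_points <- as.integer(n_points)
  if (is.na(n_points) || n_points < 2L) {
    stop_config("n_points", "must be an integer >= 2")
  }
  structure(
    list(start = as.numeric(start), end = as.numeric(end),
         n_points = n_points,
         wavenumbers = seq(start, end, length.out = n_points)),
    class = "wavenumber_grid"
  )
}

#' @export
print.wavenumber_grid <- function(x, ...) {
  cat(sprintf("<wavenumber_grid> %g..%g cm^-1, %d points (step %.4g)\n",
              x$start, x$end, x$n_points,
              (x$end - x$start) / (x$n_points - 1)))
  invisible(x)
}

grid_equal <- function(a, b) {
  isTRUE(all.equal(a$wavenumbers, b$wavenumbers, tolerance = 1e-12))
}

#' Trapezoidal area under a spectrum
#'
#' @param x wavenumber vector (or a `wavenumber_grid`).
#' @param y intensity vector of the same length.
#' @return scalar trapezoidal integral.
#' @export
trapz_area <- function(x, y) {
  if (inherits(x, "wavenumber_grid")) x <- x$wavenumbers
  stopifnot(length(x) == length(y))
  n <- length(x)
  sum((y[-1] + y[-n]) * diff(x)) / 2
}

# Lorentzian line shape with unit peak height at `center`; `width` is the
# half-width at half-maximum in cm^-1.
lorentzian <- function(wavenumbers, center, width) {
  1 / (1 + ((wavenumbers - center) / width)^2)
}
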