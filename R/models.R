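# Forward dielectric relaxation models and permittivity/conductivity
# conversions. Loss-positive convention throughout: the imaginary part of the
# complex permittivity is stored as a non-negative magnitude `eps_loss`.

#' Vacuum permittivity (F/m), CODATA value
#' @keywords internal
EPS0 <- 8.8541878128e-12

#' Construct a frequency grid
#'
#' A strictly increasing vector of measurement frequencies in Hz. The default
#' analysis band for lung-tissue spectra is 100 MHz to 1 GHz; frequencies
#' outside that band are allowed but trigger a warning, since the first-order
#' relaxation model is only intended in-band.
#'
#' @param freqs_hz numeric vector of frequencies in Hz, strictly increasing,
#'   all positive.
#' @return An object of class `freq_grid`.
#' @seealso [default_grid()]
#' @export
freq_grid <- function(freqs_hz) {
  freqs_hz <- as.numeric(freqs_hz)
  if (length(freqs_hz) < 1L) stop("freq_grid: at least one frequency required")
  if (any(!is.finite(freqs_hz)) || any(freqs_hz <= 0)) {
    stop("freq_grid: frequencies must be finite and > 0")
  }
  if (length(freqs_hz) > 1L && any(diff(freqs_hz) <= 0)) {
    stop("freq_grid: frequencies must be strictly increasing")
  }
  if (any(freqs_hz < 1e8) || any(freqs_hz > 1e9)) {
    warning("freq_grid: frequencies outside the 100 MHz-1 GHz analysis band")
  }
  structure(list(freqs_hz = freqs_hz), class = "freq_grid")
}

#' Default analysis grid: 101 linear points from 100 MHz to 1 GHz
#'
#' @param n_points number of points (>= 2)
#' @param f_min,f_max band edges in Hz
#' @return A `freq_grid`.
#' @export
default_grid <- function(n_points = 101L, f_min = 1e8, f_max = 1e9) {
  if (n_points < 2L) stop("default_grid: n_points must be >= 2")
  if (f_min >= f_max) stop("default_grid: f_min must be < f_max")
  freq_grid(seq(f_min, f_max, length.out = n_points))
}

#' Construct a dielectric spectrum
#'
#' Holds the complex relative permittivity sampled on a frequency grid,
#' split into its real part (`eps_real`, the dielectric constant) and the
#' magnitude of its imaginary part (`eps_loss`, the loss factor). The loss is
#' stored as a non-negative magnitude regardless of sign convention; the
#' underlying complex permittivity is `eps_real - 1i * eps_loss`.
#'
#' @param grid a [freq_grid()]
#' @param eps_real numeric vector, finite, same length as the grid
#' @param eps_loss numeric vector, non-negative, same length as the grid
#' @return An object of class `dielectric_spectrum`.
#' @export
dielectric_spectrum <- function(grid, eps_real, eps_loss) {
  stopifnot(inherits(grid, "freq_grid"))
  n <- length(grid$freqs_hz)
  eps_real <- as.numeric(eps_real)
  eps_loss <- as.numeric(eps_loss)
  if (length(eps_real) != n || length(eps_loss) != n) {
    stop("dielectric_spectrum: component lengths must match the grid")
  }
  if (any(!is.finite(eps_real)) || any(!is.finite(eps_loss))) {
    stop("dielectric_spectrum: components must be finite")
  }
  if (any(eps_loss < 0)) {
    stop("dielectric_spectrum: eps_loss must be non-negative (loss-positive convention)")
  }
  structure(list(grid = grid, eps_real = eps_real, eps_loss = eps_loss),
            class = "dielectric_spectrum")
}

#' @export
print.dielectric_spectrum <- function(x, ...) {
  f <- x$grid$freqs_hz
  cat(sprintf("<dielectric_spectrum: %d points, %.3g-%.3g Hz>\n",
              length(f), min(f), max(f)))
  cat(sprintf("  eps_real in [%.4g, %.4g], eps_loss in [%.4g, %.4g]\n",
              min(x$eps_real), max(x$eps_real),
              min(x$eps_loss), max(x$eps_loss)))
  invisible(x)
}

#' Cole-Cole model parameters
#'
#' First-order Cole-Cole relaxation:
#' eps*(w) = eps_inf + delta_eps / (1 + (1i w tau)^(1 - alpha)) +
#' sigma_s / (1i w eps0), with w = 2 pi f the angular frequency.
#'
#' @param eps_inf high-frequency permittivity limit (> 0, dimensionless)
#' @param delta_eps dispersion magnitude (>= 0, dimensionless)
#' @param tau_s relaxation time in seconds (> 0; order picoseconds for tissue
#'   water relaxation tails in the 100 MHz-1 GHz band)
#' @param alpha relaxation-time distribution broadening, in `[0, 1)`; 0 gives
#'   the Debye model
#' @param sigma_s static (ionic) conductivity in S/m (>= 0)
#' @return An object of class `cole_cole_params`.
#' @export
cole_cole_params <- function(eps_inf, delta_eps, tau_s, alpha = 0, sigma_s = 0) {
  p <- list(eps_inf = as.numeric(eps_inf), delta_eps = as.numeric(delta_eps),
            tau_s = as.numeric(tau_s), alpha = as.numeric(alpha),
            sigma_s = as.numeric(sigma_s))
  if (any(!vapply(p, is.finite, logical(1L)))) {
    stop("cole_cole_params: all parameters must be finite scalars")
  }
  if (p$eps_inf <= 0) stop("cole_cole_params: eps_inf must be > 0")
  if (p$delta_eps < 0) stop("cole_cole_params: delta_eps must be >= 0")
  if (p$tau_s <= 0) stop("cole_cole_params: tau_s must be > 0")
  if (p$alpha < 0 || p$alpha >= 1) stop("cole_cole_params: alpha must be in [0, 1)")
  if (p$sigma_s < 0) stop("cole_cole_params: sigma_s must be >= 0")
  structure(p, class = "cole_cole_params")
}

#' Improved (linear frequency-augmented) Cole-Cole parameters
#'
#' Adds a purely real term `A * w` (w in rad/s) to the Cole-Cole expression,
#' capturing the weak extra frequency dependence that air content induces in
#' ventilated lung tissue. `a_coef` has units of seconds per radian so that
#' `A * w` is dimensionless; tabulated magnitudes are of order 1e-9.
#'
#' @param base a [cole_cole_params()] object, or `eps_inf` if the remaining
#'   scalar parameters are given
#' @param a_coef linear angular-frequency coefficient (s/rad), |a_coef| <= 1e-6
#' @param delta_eps,tau_s,alpha,sigma_s passed to [cole_cole_params()] when
#'   `base` is a scalar `eps_inf`
#' @return An object of class `improved_cole_cole_params` with fields `base`
#'   and `a_coef`.
#' @export
improved_cole_cole_params <- function(base, a_coef, delta_eps = NULL,
                                      tau_s = NULL, alpha = 0, sigma_s = 0) {
  if (!inherits(base, "cole_cole_params")) {
    base <- cole_cole_params(base, delta_eps, tau_s, alpha, sigma_s)
  }
  a_coef <- as.numeric(a_coef)
  if (!is.finite(a_coef) || abs(a_coef) > 1e-6) {
    stop("improved_cole_cole_params: a_coef must be finite with |a_coef| <= 1e-6")
  }
  structure(list(base = base, a_coef = a_coef),
            class = "improved_cole_cole_params")
}

# Complex permittivity of the Cole-Cole relaxation + conduction terms at
# angular frequencies w (rad/s). alpha == 0 is special-cased so the Debye
# reduction is exact to machine precision (the principal-branch power would
# otherwise leave cos(pi/2) ~ 6e-17 residue in the real part).
cole_cole_complex <- function(p, w) {
  if (p$alpha == 0) {
    denom <- complex(real = 1, imaginary = w * p$tau_s)
  } else {
    # (1i w tau)^(1-alpha), principal branch: (w tau)^(1-alpha) * e^{i pi (1-alpha)/2}
    mag <- (w * p$tau_s)^(1 - p$alpha)
    ang <- pi / 2 * (1 - p$alpha)
    denom <- 1 + complex(modulus = mag, argument = ang)
  }
  relax <- p$delta_eps / denom
  cond <- complex(real = 0, imaginary = -p$sigma_s / (w * EPS0))
  p$eps_inf + relax + cond
}

as_spectrum <- function(z, grid, what) {
  if (any(!is.finite(Re(z))) || any(!is.finite(Im(z)))) {
    bad <- grid$freqs_hz[which(!is.finite(Re(z)) | !is.finite(Im(z)))[1L]]
    stop(sprintf("%s: non-finite permittivity at f = %g Hz (invalid parameters)",
                 what, bad))
  }
  dielectric_spectrum(grid, Re(z), abs(Im(z)))
}

#' Evaluate the Cole-Cole model on a frequency grid
#'
#' Computes eps*(w) = eps_inf + delta_eps / (1 + (1i w tau)^(1 - alpha)) +
#' sigma_s / (1i w eps0) at w = 2 pi f and returns the real part and the loss
#' magnitude.
#'
#' @param params a [cole_cole_params()]
#' @param grid a [freq_grid()]
#' @return A [dielectric_spectrum()].
#' @examples
#' sp <- evaluate_cole_cole(cole_cole_params(3.48, 58.52, 6.04e-12,
#'                                           sigma_s = 19.96e-3),
#'                          default_grid())
#' @export
evaluate_cole_cole <- function(params, grid) {
  stopifnot(inherits(params, "cole_cole_params"), inherits(grid, "freq_grid"))
  w <- 2 * pi * grid$freqs_hz
  as_spectrum(cole_cole_complex(params, w), grid, "evaluate_cole_cole")
}

#' Evaluate the improved Cole-Cole model on a frequency grid
#'
#' As [evaluate_cole_cole()] plus the purely real linear term `a_coef * w`
#' with w the angular frequency in rad/s. Signals an error if the resulting
#' real part is non-positive anywhere on the grid (unphysical combination).
#'
#' @param params an [improved_cole_cole_params()]
#' @param grid a [freq_grid()]
#' @return A [dielectric_spectrum()].
#' @export
evaluate_improved <- function(params, grid) {
  stopifnot(inherits(params, "improved_cole_cole_params"),
            inherits(grid, "freq_grid"))
  w <- 2 * pi * grid$freqs_hz
  z <- cole_cole_complex(params$base, w) + params$a_coef * w
  sp <- as_spectrum(z, grid, "evaluate_improved")
  if (any(sp$eps_real <= 0)) {
    bad <- grid$freqs_hz[which(sp$eps_real <= 0)[1L]]
    stop(sprintf(
      "evaluate_improved: eps_real <= 0 at f = %g Hz (unphysical parameters)", bad))
  }
  sp
}

#' Effective conductivity of a spectrum
#'
#' Converts the loss factor to an effective conductivity per frequency,
#' sigma(w) = w * eps0 * eps_loss — the inverse of the static-conduction
#' relation eps_loss = sigma_s / (w eps0).
#'
#' @param spectrum a [dielectric_spectrum()]
#' @return Numeric vector of conductivities in S/m, one per grid frequency.
#' @export
effective_conductivity <- function(spectrum) {
  stopifnot(inherits(spectrum, "dielectric_spectrum"))
  2 * pi * spectrum$grid$freqs_hz * EPS0 * spectrum$eps_loss
}

#' Loss factor implied by a conductivity
#'
#' @param conductivity numeric vector in S/m
#' @param grid a [freq_grid()] of matching length
#' @return Numeric vector of non-negative loss magnitudes.
#' @export
loss_from_conductivity <- function(conductivity, grid) {
  stopifnot(inherits(grid, "freq_grid"))
  conductivity <- as.numeric(conductivity)
  if (length(conductivity) != length(grid$freqs_hz)) {
    stop("loss_from_conductivity: length mismatch with grid")
  }
  if (any(conductivity < 0)) stop("loss_from_conductivity: conductivity must be >= 0")
  conductivity / (2 * pi * grid$freqs_hz * EPS0)
}
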