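# Fit-quality metrics: relative average fitting error and per-component R^2.

same_grid <- function(a, b) {
  length(a$grid$freqs_hz) == length(b$grid$freqs_hz) &&
    all(a$grid$freqs_hz == b$grid$freqs_hz)
}

# Unchecked numeric core shared by average_error() and the SA objective.
# A component where measured and fitted are both exactly zero agrees
# perfectly and contributes nothing; a zero fitted value against a nonzero
# measured one yields Inf, which the optimizer rejects and the exported
# metric turns into an error.
avg_error_core <- function(m_real, m_loss, f_real, f_loss) {
  if (any(f_real == 0 & m_real != 0) || any(f_loss == 0 & m_loss != 0)) {
    return(Inf)
  }
  rel_r <- ifelse(f_real == 0, 0, (m_real - f_real) / f_real)
  rel_i <- ifelse(f_loss == 0, 0, (m_loss - f_loss) / f_loss)
  100 * mean(sqrt(rel_r^2 + rel_i^2))
}

#' Average fitting error between two spectra (percent)
#'
#' Per-frequency Euclidean norm of the relative errors of the real and loss
#' components, averaged over the grid and expressed in percent:
#' `100/N * sum_i sqrt(((Re m - Re f)/Re f)^2 + ((Im m - Im f)/Im f)^2)`,
#' with `m` the measured and `f` the fitted spectrum. Both spectra use the
#' loss-positive convention, so the value is sign-convention invariant.
#'
#' @param measured,fitted [dielectric_spectrum()] objects on identical grids
#' @return Scalar percentage (>= 0).
#' @examples
#' g <- default_grid(5)
#' a <- dielectric_spectrum(g, rep(50, 5), rep(5, 5))
#' average_error(a, a)  # 0
#' @details A grid point where a fitted component is exactly zero while the
#' measured one is not has an undefined relative error and raises an error
#' naming the frequency; a point where both are zero agrees exactly and
#' contributes zero.
#' @export
average_error <- function(measured, fitted) {
  stopifnot(inherits(measured, "dielectric_spectrum"),
            inherits(fitted, "dielectric_spectrum"))
  if (!same_grid(measured, fitted)) {
    stop("average_error: spectra must share an identical frequency grid")
  }
  zero <- (fitted$eps_real == 0 & measured$eps_real != 0) |
    (fitted$eps_loss == 0 & measured$eps_loss != 0)
  if (any(zero)) {
    stop(sprintf("average_error: fitted component is zero at f = %g Hz",
                 fitted$grid$freqs_hz[which(zero)[1L]]))
  }
  avg_error_core(measured$eps_real, measured$eps_loss,
                 fitted$eps_real, fitted$eps_loss)
}

#' Coefficient of determination for one spectrum component
#'
#' `R^2 = 1 - SSres/SStot` with `SSres = sum((measured - fitted)^2)` and
#' `SStot = sum((measured - mean(measured))^2)`. Computed separately for the
#' real and loss components of a fit.
#'
#' @param measured,fitted numeric vectors of equal length >= 2
#' @return Scalar, at most 1 (can be negative for fits worse than the mean).
#' @export
r_squared <- function(measured, fitted) {
  measured <- as.numeric(measured)
  fitted <- as.numeric(fitted)
  if (length(measured) != length(fitted) || length(measured) < 2L) {
    stop("r_squared: vectors must have equal length >= 2")
  }
  ss_tot <- sum((measured - mean(measured))^2)
  if (ss_tot == 0) {
    stop("r_squared: measured component has zero variance; R^2 undefined")
  }
  1 - sum((measured - fitted)^2) / ss_tot
}
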