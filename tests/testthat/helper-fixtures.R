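# Shared fixtures. Frozen oracle values were computed with an independent
# term-by-term numpy evaluation script written before the R implementation.

EPS0_REF <- 8.8541878128e-12

# Tabulated generating parameters (SI units), keyed by tidal volume in mL.
table3_truth <- list(
  `30` = c(eps_inf = 3.48, delta_eps = 58.52, tau_s = 6.04e-12, alpha = 0,
           sigma_s = 19.96e-3, a_coef = -3.66e-9),
  `40` = c(eps_inf = 3.22, delta_eps = 57.81, tau_s = 5.91e-12, alpha = 0,
           sigma_s = 17.56e-3, a_coef = -3.74e-9),
  `50` = c(eps_inf = 3.63, delta_eps = 58.59, tau_s = 5.15e-12, alpha = 0,
           sigma_s = 10.48e-3, a_coef = -3.74e-9),
  `60` = c(eps_inf = 2.28, delta_eps = 56.43, tau_s = 4.93e-12, alpha = 0,
           sigma_s = 7.90e-3, a_coef = -3.68e-9),
  `70` = c(eps_inf = 3.81, delta_eps = 55.07, tau_s = 5.31e-12, alpha = 0,
           sigma_s = 6.61e-3, a_coef = -3.82e-9),
  `80` = c(eps_inf = 2.13, delta_eps = 54.01, tau_s = 5.02e-12, alpha = 0,
           sigma_s = 4.55e-3, a_coef = -3.53e-9))

truth_params <- function(vt) {
  v <- table3_truth[[as.character(vt)]]
  improved_cole_cole_params(
    cole_cole_params(v[["eps_inf"]], v[["delta_eps"]], v[["tau_s"]],
                     alpha = v[["alpha"]], sigma_s = v[["sigma_s"]]),
    v[["a_coef"]])
}

# Frozen values from the independent evaluation oracle.
oracle <- list(
  cc_vt30_433 = c(real = 61.984202205211, loss = 1.789970962887),
  imp_vt80_915 = c(real = 35.800676418860, loss = 1.646845715473),
  imp_vt30_433 = c(real = 52.026735794099, loss = 1.789970962887),
  sigma_eff_vt30_433 = 0.043118384452,
  # 5-point metric fixture (measured vs fitted components):
  five_pt = list(
    m_re = c(52.1, 48.3, 45.0, 42.7, 41.1),
    m_im = c(9.4, 7.2, 6.1, 5.5, 5.2),
    f_re = c(51.8, 48.9, 44.6, 42.9, 40.8),
    f_im = c(9.1, 7.5, 6.0, 5.6, 5.0),
    err = 3.067277733897073,
    r2_real = 0.990545789043336,
    r2_imag = 0.979288919571971))

five_pt_spectra <- function() {
  g <- freq_grid(seq(2e8, 8e8, length.out = 5))
  list(measured = dielectric_spectrum(g, oracle$five_pt$m_re, oracle$five_pt$m_im),
       fitted = dielectric_spectrum(g, oracle$five_pt$f_re, oracle$five_pt$f_im))
}

# Reduced annealing budget for tests that exercise behaviour rather than
# sub-percent recovery precision.
quick_config <- function(seed = 1L, ...) {
  fit_config(seed = seed, n_restarts = 2L, max_evaluations = 8e3,
             iterations_per_temperature = 100L, ...)
}

rel_err <- function(est, truth) abs(est - truth) / abs(truth)

fitted_theta <- function(fit) {
  b <- if (fit$model == "improved") fit$params$base else fit$params
  out <- c(eps_inf = b$eps_inf, delta_eps = b$delta_eps, tau_s = b$tau_s,
           alpha = b$alpha, sigma_s = b$sigma_s)
  if (fit$model == "improved") out <- c(out, a_coef = fit$params$a_coef)
  out
}
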