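# Synthetic measurement-like spectra across tidal volumes. Stands in for the
# unreleased animal data: the packaged parameter table drives the improved
# forward model, replicate structure mirrors the triplicate probe
# measurements, and noise is independent multiplicative Gaussian per
# component per frequency (default cv 2%, inside the probe's validated +/-5%
# error envelope).

#' Packaged tidal-volume parameter table
#'
#' Improved Cole-Cole parameters of in vivo lung tissue at the six ventilator
#' tidal volumes 30-80 mL, loaded from the plain-text fixture shipped with
#' the package and converted to SI units (tau ps -> s, sigma_s 1e-3 S/m ->
#' S/m, a_coef 1e-9 -> s/rad).
#'
#' @param path CSV file to load; defaults to the packaged table
#' @return An object of class `tidal_volume_table`: a named list mapping
#'   `"30" ... "80"` to [improved_cole_cole_params()] objects, with the raw
#'   table kept in attribute `table`.
#' @export
tidal_volume_table <- function(path = system.file("extdata",
                                                  "tidal_volume_params.csv",
                                                  package = "dielspec")) {
  raw <- utils::read.csv(path, comment.char = "#")
  need <- c("vt_ml", "eps_inf", "delta_eps", "tau_ps", "alpha",
            "sigma_s_mS_per_m", "a_coef_1e9")
  if (!all(need %in% names(raw))) {
    stop("tidal_volume_table: missing columns: ",
         paste(setdiff(need, names(raw)), collapse = ", "))
  }
  entries <- lapply(seq_len(nrow(raw)), function(i) {
    improved_cole_cole_params(
      cole_cole_params(raw$eps_inf[i], raw$delta_eps[i], raw$tau_ps[i] * 1e-12,
                       alpha = raw$alpha[i],
                       sigma_s = raw$sigma_s_mS_per_m[i] * 1e-3),
      raw$a_coef_1e9[i] * 1e-9)
  })
  names(entries) <- as.character(raw$vt_ml)
  structure(entries, table = raw, class = "tidal_volume_table")
}

#' Measurement-noise model for synthetic spectra
#'
#' Each spectrum component is the noiseless forward-model value multiplied by
#' an independent `1 + Normal(0, cv)` factor, per frequency, per component,
#' per replicate; loss values are clipped at zero.
#'
#' @param cv_real,cv_loss relative standard deviations (>= 0) of the
#'   multiplicative noise on the real and loss components
#' @param replicates spectra per condition (>= 1; the in vivo protocol used 3)
#' @param seed integer seed
#' @return An object of class `noise_model`.
#' @export
noise_model <- function(cv_real = 0.02, cv_loss = 0.02, replicates = 3L,
                        seed = 1L) {
  if (cv_real < 0 || cv_loss < 0) stop("noise_model: cv must be >= 0")
  if (replicates < 1L) stop("noise_model: replicates must be >= 1")
  structure(list(cv_real = cv_real, cv_loss = cv_loss,
                 replicates = as.integer(replicates), seed = as.integer(seed)),
            class = "noise_model")
}

#' Generate noisy replicate spectra from one parameter set
#'
#' @param params an [improved_cole_cole_params()] (or [cole_cole_params()])
#' @param grid a [freq_grid()]
#' @param noise a [noise_model()]
#' @return List of `noise$replicates` [dielectric_spectrum()] objects;
#'   deterministic given `noise$seed`.
#' @export
generate_spectrum <- function(params, grid, noise = noise_model()) {
  stopifnot(inherits(grid, "freq_grid"), inherits(noise, "noise_model"))
  clean <- if (inherits(params, "improved_cole_cole_params")) {
    evaluate_improved(params, grid)
  } else {
    evaluate_cole_cole(params, grid)
  }
  n <- length(grid$freqs_hz)
  local_seed(noise$seed, {
    lapply(seq_len(noise$replicates), function(r) {
      re <- clean$eps_real * (1 + stats::rnorm(n, 0, noise$cv_real))
      lo <- clean$eps_loss * (1 + stats::rnorm(n, 0, noise$cv_loss))
      dielectric_spectrum(grid, re, pmax(lo, 0))
    })
  })
}

#' Generate a labelled multi-tidal-volume dataset
#'
#' One replicate set per tidal volume, generated from the parameter table by
#' the improved forward model under the given noise law. Replicate seeds are
#' derived deterministically from `noise$seed` and the condition index so
#' conditions are independent but the whole dataset is reproducible.
#'
#' @param table a [tidal_volume_table()]
#' @param grid a [freq_grid()]
#' @param noise a [noise_model()]
#' @return An object of class `vt_dataset`: list with `spectra` (list of
#'   [dielectric_spectrum()]), parallel vectors `vt_ml` and `replicate`,
#'   `grid`, `noise` and the generating `table`.
#' @export
generate_vt_dataset <- function(table = tidal_volume_table(),
                                grid = default_grid(),
                                noise = noise_model()) {
  stopifnot(inherits(table, "tidal_volume_table"))
  spectra <- list()
  vt_lab <- integer(0)
  rep_lab <- integer(0)
  for (i in seq_along(table)) {
    sub <- noise_model(noise$cv_real, noise$cv_loss, noise$replicates,
                       seed = (noise$seed + 7919L * i) %% .Machine$integer.max)
    reps <- generate_spectrum(table[[i]], grid, sub)
    spectra <- c(spectra, reps)
    vt_lab <- c(vt_lab, rep.int(as.integer(names(table)[i]), length(reps)))
    rep_lab <- c(rep_lab, seq_along(reps))
  }
  structure(list(spectra = spectra, vt_ml = vt_lab, replicate = rep_lab,
                 grid = grid, noise = noise, table = table),
            class = "vt_dataset")
}

#' @export
print.vt_dataset <- function(x, ...) {
  cat(sprintf("<vt_dataset: %d spectra (%d tidal volumes x %d replicates), %d-point grid>\n",
              length(x$spectra), length(unique(x$vt_ml)),
              max(x$replicate), length(x$grid$freqs_hz)))
  invisible(x)
}

#' Linear-in-VT interpolation of the parameter table
#'
#' Interpolates each parameter linearly in tidal volume between the tabulated
#' conditions. This is an extrapolation device for simulation studies only:
#' the tabulated rows are fitted point estimates and nothing in the
#' measurements constrains intermediate volumes.
#'
#' @param table a [tidal_volume_table()]
#' @param vt_ml tidal volume in mL, within the tabulated range
#' @return An [improved_cole_cole_params()].
#' @export
interpolate_vt_params <- function(table, vt_ml) {
  stopifnot(inherits(table, "tidal_volume_table"))
  raw <- attr(table, "table")
  if (vt_ml < min(raw$vt_ml) || vt_ml > max(raw$vt_ml)) {
    stop("interpolate_vt_params: vt_ml outside the tabulated range")
  }
  ip <- function(col) stats::approx(raw$vt_ml, raw[[col]], xout = vt_ml)$y
  improved_cole_cole_params(
    cole_cole_params(ip("eps_inf"), ip("delta_eps"), ip("tau_ps") * 1e-12,
                     alpha = ip("alpha"), sigma_s = ip("sigma_s_mS_per_m") * 1e-3),
    ip("a_coef_1e9") * 1e-9)
}
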