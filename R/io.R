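# Plain-text interchange: spectrum CSV with a commented convention header,
# parameter/result JSON. Units on disk are Hz, dimensionless permittivity,
# S/m and seconds; picosecond display conversion happens only when printing.

SPECTRUM_HEADER <- "# dielspec spectrum v1"

#' Write a spectrum to CSV
#'
#' Columns `frequency_hz, eps_real, eps_loss` (loss-positive convention) or,
#' with `as_conductivity = TRUE`, `frequency_hz, eps_real,
#' conductivity_S_per_m`. A commented header records the convention.
#'
#' @param spectrum a [dielectric_spectrum()]
#' @param path output file
#' @param as_conductivity write the loss as effective conductivity instead
#' @return `path`, invisibly.
#' @export
write_spectrum <- function(spectrum, path, as_conductivity = FALSE) {
  stopifnot(inherits(spectrum, "dielectric_spectrum"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(SPECTRUM_HEADER,
               "# loss_convention: positive",
               "# units: frequency Hz, permittivity dimensionless, conductivity S/m"),
             con)
  df <- if (as_conductivity) {
    data.frame(frequency_hz = spectrum$grid$freqs_hz,
               eps_real = spectrum$eps_real,
               conductivity_S_per_m = effective_conductivity(spectrum))
  } else {
    data.frame(frequency_hz = spectrum$grid$freqs_hz,
               eps_real = spectrum$eps_real,
               eps_loss = spectrum$eps_loss)
  }
  utils::write.csv(format(df, digits = 17, scientific = TRUE, trim = TRUE),
                   con, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a spectrum from CSV
#'
#' Accepts either an `eps_loss` or a `conductivity_S_per_m` column (exactly
#' one); conductivity is converted to a loss factor via
#' `eps_loss = sigma / (2 pi f eps0)`. Non-monotone frequencies, missing
#' columns and non-finite values raise parse errors naming the offending
#' data line.
#'
#' @param path CSV file as written by [write_spectrum()]
#' @return A [dielectric_spectrum()].
#' @export
read_spectrum <- function(path) {
  if (!file.exists(path)) stop("read_spectrum: no such file: ", path)
  lines <- readLines(path)
  is_comment <- startsWith(trimws(lines), "#") | trimws(lines) == ""
  body <- lines[!is_comment]
  body_lineno <- which(!is_comment)
  if (length(body) < 2L) stop("read_spectrum: no data rows in ", path)
  df <- utils::read.csv(text = body, stringsAsFactors = FALSE)
  if (!"frequency_hz" %in% names(df)) {
    stop("read_spectrum: missing frequency_hz column in ", path)
  }
  has_loss <- "eps_loss" %in% names(df)
  has_cond <- "conductivity_S_per_m" %in% names(df)
  if (!"eps_real" %in% names(df) || has_loss == has_cond) {
    stop("read_spectrum: need eps_real plus exactly one of eps_loss / conductivity_S_per_m in ",
         path)
  }
  data_lineno <- body_lineno[-1L]  # file line of each data row
  loss_col <- if (has_loss) df$eps_loss else df$conductivity_S_per_m
  bad <- !is.finite(df$frequency_hz) | !is.finite(df$eps_real) | !is.finite(loss_col)
  if (any(bad)) {
    stop(sprintf("read_spectrum: non-finite value at line %d of %s",
                 data_lineno[which(bad)[1L]], path))
  }
  nondec <- which(diff(df$frequency_hz) <= 0)
  if (length(nondec) > 0L) {
    stop(sprintf(
      "read_spectrum: frequencies not strictly increasing at line %d of %s",
      data_lineno[nondec[1L] + 1L], path))
  }
  grid <- freq_grid(df$frequency_hz)
  loss <- if (has_loss) df$eps_loss else loss_from_conductivity(df$conductivity_S_per_m, grid)
  dielectric_spectrum(grid, df$eps_real, loss)
}

params_to_list <- function(params) {
  if (inherits(params, "improved_cole_cole_params")) {
    c(unclass(params$base), list(a_coef = params$a_coef, model = "improved"))
  } else {
    c(unclass(params), list(model = "cole_cole"))
  }
}

list_to_params <- function(lst) {
  base <- cole_cole_params(lst$eps_inf, lst$delta_eps, lst$tau_s,
                           alpha = lst$alpha, sigma_s = lst$sigma_s)
  if (identical(lst$model, "improved") || !is.null(lst$a_coef)) {
    improved_cole_cole_params(base, lst$a_coef)
  } else {
    base
  }
}

#' Write model parameters to JSON
#'
#' @param params a [cole_cole_params()] or [improved_cole_cole_params()]
#' @param path output file
#' @return `path`, invisibly.
#' @export
write_params_json <- function(params, path) {
  jsonlite::write_json(params_to_list(params), path, auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' Read model parameters from JSON
#'
#' @param path file written by [write_params_json()]
#' @return A parameter object.
#' @export
read_params_json <- function(path) {
  list_to_params(jsonlite::read_json(path, simplifyVector = TRUE))
}

#' Write a fit result to JSON
#'
#' Serialises all fields of a `diel_fit`, with parameters inline, plus the
#' package version.
#'
#' @param fit a `diel_fit` from [fit_improved()] or [fit_cole_cole()]
#' @param path output file
#' @return `path`, invisibly.
#' @export
write_fit_result <- function(fit, path) {
  stopifnot(inherits(fit, "diel_fit"))
  out <- list(model = fit$model,
              params = params_to_list(fit$params),
              err_bar_pct = fit$err_bar_pct,
              r2_real = fit$r2_real,
              r2_imag = fit$r2_imag,
              n_evaluations = fit$n_evaluations,
              seed = fit$seed,
              converged = fit$converged,
              package_version = as.character(utils::packageVersion("dielspec")))
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
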