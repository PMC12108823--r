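# Group comparison of dielectric quantities across tidal volumes at the ISM
# reporting frequencies (433 and 915 MHz).

#' Extract one dielectric quantity at one frequency from a dataset
#'
#' Reads out the grid point nearest the requested frequency (no
#' interpolation, matching how a VNA sweep is read) and returns one
#' observation per replicate per tidal volume. If the nearest grid point is
#' farther than half the local grid spacing a warning is recorded in the
#' result (`off_grid = TRUE`).
#'
#' @param dataset a `vt_dataset` from [generate_vt_dataset()] (all spectra on
#'   one grid)
#' @param frequency_hz requested frequency in Hz
#' @param quantity `"permittivity"` (the real part) or `"conductivity"`
#'   (effective conductivity at the selected point)
#' @return An object of class `grouped_samples`: list with `groups` (named
#'   list of numeric vectors, one per tidal volume), `quantity`,
#'   `frequency_hz` (the selected grid frequency), `requested_hz`,
#'   `off_grid`.
#' @export
extract_at_frequency <- function(dataset, frequency_hz,
                                 quantity = c("conductivity", "permittivity")) {
  quantity <- match.arg(quantity)
  stopifnot(inherits(dataset, "vt_dataset"))
  f <- dataset$grid$freqs_hz
  idx <- which.min(abs(f - frequency_hz))
  spacing <- if (length(f) > 1L) {
    stats::median(diff(f))
  } else {
    Inf
  }
  off_grid <- abs(f[idx] - frequency_hz) > spacing / 2 + 1e-9 * spacing
  if (off_grid) {
    warning(sprintf(
      "extract_at_frequency: nearest grid point %.6g Hz is farther than half the grid spacing from %.6g Hz",
      f[idx], frequency_hz))
  }
  obs <- vapply(dataset$spectra, function(sp) {
    if (quantity == "permittivity") {
      sp$eps_real[idx]
    } else {
      2 * pi * f[idx] * EPS0 * sp$eps_loss[idx]
    }
  }, numeric(1L))
  groups <- split(obs, dataset$vt_ml)
  structure(list(groups = groups, quantity = quantity,
                 frequency_hz = f[idx], requested_hz = frequency_hz,
                 off_grid = off_grid),
            class = "grouped_samples")
}

#' Group scalar observations for a rank test
#'
#' @param groups named list of non-empty numeric vectors (>= 2 groups)
#' @param quantity,frequency_hz optional labels carried in the result
#' @return A `grouped_samples` object.
#' @export
grouped_samples <- function(groups, quantity = NA_character_,
                            frequency_hz = NA_real_) {
  if (!is.list(groups) || length(groups) < 2L) {
    stop("grouped_samples: need at least 2 groups")
  }
  if (any(vapply(groups, length, integer(1L)) == 0L)) {
    stop("grouped_samples: every group must be non-empty")
  }
  structure(list(groups = lapply(groups, as.numeric), quantity = quantity,
                 frequency_hz = frequency_hz, requested_hz = frequency_hz,
                 off_grid = FALSE),
            class = "grouped_samples")
}

#' Kruskal-Wallis rank test across groups
#'
#' Tie-corrected H statistic on midranks with a chi-square p-value on k - 1
#' degrees of freedom:
#' `H = [12 / (N (N+1)) * sum_g n_g (Rbar_g - (N+1)/2)^2] / C`, where the tie
#' correction `C = 1 - sum(t^3 - t) / (N^3 - N)` runs over tie-block sizes.
#' When every observation is tied, H is defined as 0 with p = 1.
#'
#' @param samples a `grouped_samples` object
#' @return An object of class `group_comparison`: `h_statistic`, `df`,
#'   `p_value`, `tie_corrected` (TRUE when ties were present).
#' @export
kruskal_wallis <- function(samples) {
  stopifnot(inherits(samples, "grouped_samples"))
  groups <- samples$groups
  k <- length(groups)
  if (k < 2L) stop("kruskal_wallis: need at least 2 groups")
  x <- unlist(groups, use.names = FALSE)
  n_g <- vapply(groups, length, integer(1L))
  n <- length(x)
  if (n < k + 1L) stop("kruskal_wallis: need total N >= number of groups + 1")
  r <- rank(x)  # midranks
  g <- rep.int(seq_len(k), n_g)
  rbar <- vapply(split(r, g), mean, numeric(1L))
  h <- 12 / (n * (n + 1)) * sum(n_g * (rbar - (n + 1) / 2)^2)
  ties <- tabulate(match(x, unique(x)))  # tie-block sizes, exact equality
  correction <- 1 - sum(ties^3 - ties) / (n^3 - n)
  tie_corrected <- any(ties > 1L)
  if (correction == 0) {
    h <- 0          # all observations identical
    p <- 1
  } else {
    h <- h / correction
    p <- stats::pchisq(h, df = k - 1, lower.tail = FALSE)
  }
  structure(list(h_statistic = h, df = k - 1L, p_value = p,
                 tie_corrected = tie_corrected,
                 quantity = samples$quantity,
                 frequency_hz = samples$frequency_hz),
            class = "group_comparison")
}

#' @export
print.group_comparison <- function(x, ...) {
  lab <- if (!is.na(x$quantity)) {
    sprintf(" [%s @ %.4g Hz]", x$quantity, x$frequency_hz)
  } else {
    ""
  }
  cat(sprintf("Kruskal-Wallis%s: H = %.4g, df = %d, p = %.4g\n",
              lab, x$h_statistic, x$df, x$p_value))
  invisible(x)
}

#' Normality check with distribution-appropriate summaries
#'
#' Runs a Shapiro-Wilk composite normality test and returns the summary
#' statistics appropriate to the verdict at the given significance level:
#' mean and SD when normality is not rejected, median and quartiles
#' otherwise. Constant samples have zero variance and raise an error.
#'
#' @param x numeric sample, n >= 3 (Shapiro-Wilk supports up to 5000)
#' @param alpha significance level steering the summary choice
#' @return List: `statistic`, `p_value`, `normal` (logical), `summary`
#'   (named numeric: mean/sd or median/q1/q3).
#' @export
normality_check <- function(x, alpha = 0.05) {
  x <- as.numeric(x)
  if (length(x) < 3L) stop("normality_check: need n >= 3")
  if (stats::sd(x) == 0) stop("normality_check: sample is constant; test undefined")
  sw <- stats::shapiro.test(x)
  normal <- sw$p.value > alpha
  summary <- if (normal) {
    c(mean = mean(x), sd = stats::sd(x))
  } else {
    q <- stats::quantile(x, c(0.25, 0.5, 0.75), names = FALSE)
    c(median = q[2L], q1 = q[1L], q3 = q[3L])
  }
  list(statistic = unname(sw$statistic), p_value = sw$p.value,
       normal = normal, summary = summary)
}
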