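# Forward models: reduction identities, oracle values, conversions.

test_that("type constructors enforce their invariants", {
  expect_error(freq_grid(c(2e8, 2e8, 3e8)), "strictly increasing")
  expect_error(freq_grid(numeric(0)), "at least one")
  expect_error(freq_grid(c(-1e8, 2e8)), "> 0")
  expect_warning(freq_grid(c(5e7, 2e8)), "outside")
  g <- default_grid()
  expect_length(g$freqs_hz, 101L)
  expect_equal(range(g$freqs_hz), c(1e8, 1e9))
  expect_error(dielectric_spectrum(g, rep(1, 100), rep(0, 101)), "length")
  expect_error(dielectric_spectrum(g, rep(1, 101), rep(-1, 101)), "non-negative")
  expect_error(cole_cole_params(3, -1, 1e-12), "delta_eps")
  expect_error(cole_cole_params(3, 1, 1e-12, alpha = 1), "alpha")
  expect_error(improved_cole_cole_params(cole_cole_params(3, 1, 1e-12), 1e-3),
               "a_coef")
})

test_that("dispersion-free and Debye special points are exact", {
  g <- freq_grid(5e8)
  # all dispersive/conductive terms vanish
  sp <- evaluate_cole_cole(cole_cole_params(3.1, 0, 1e-12), g)
  expect_identical(sp$eps_real, 3.1)
  expect_identical(sp$eps_loss, 0)
  # Debye at omega*tau = 1: eps* = eps_inf + delta_eps * (1 - 1i) / 2
  tau <- 1 / (2 * pi * 5e8)
  sp <- evaluate_cole_cole(cole_cole_params(3.0, 40, tau), g)
  expect_equal(sp$eps_real, 3.0 + 20, tolerance = 1e-15)
  expect_equal(sp$eps_loss, 20, tolerance = 1e-15)
  # only the linear term survives in the improved model
  g2 <- default_grid(11)
  p <- improved_cole_cole_params(cole_cole_params(4, 0, 1e-12), -2e-10)
  sp <- evaluate_improved(p, g2)
  expect_equal(sp$eps_real, 4 - 2e-10 * 2 * pi * g2$freqs_hz, tolerance = 1e-15)
  expect_identical(sp$eps_loss, rep(0, 11))
})

test_that("improved model with A = 0 reduces exactly to Cole-Cole", {
  g <- default_grid()
  set.seed(11)
  for (i in 1:20) {
    base <- cole_cole_params(runif(1, 2, 5), runif(1, 0, 80),
                             runif(1, 1e-12, 2e-11), runif(1, 0, 0.4),
                             runif(1, 0, 0.05))
    a <- evaluate_cole_cole(base, g)
    b <- evaluate_improved(improved_cole_cole_params(base, 0), g)
    expect_identical(a$eps_real, b$eps_real)
    expect_identical(a$eps_loss, b$eps_loss)
  }
})

test_that("alpha = 0 matches the closed-form Debye expression to machine precision", {
  g <- default_grid()
  w <- 2 * pi * g$freqs_hz
  set.seed(12)
  for (i in 1:20) {
    eps_inf <- runif(1, 2, 5)
    de <- runif(1, 0, 80)
    tau <- runif(1, 1e-12, 2e-11)
    sig <- runif(1, 0, 0.05)
    sp <- evaluate_cole_cole(cole_cole_params(eps_inf, de, tau, 0, sig), g)
    wt <- w * tau
    expect_equal(sp$eps_real, eps_inf + de / (1 + wt^2), tolerance = 1e-15)
    expect_equal(sp$eps_loss, de * wt / (1 + wt^2) + sig / (w * EPS0_REF),
                 tolerance = 1e-15)
  }
})

test_that("forward evaluation matches the independent oracle", {
  expect_equal(unname(unlist(
    evaluate_cole_cole(truth_params(30)$base, freq_grid(433e6))[c("eps_real", "eps_loss")])),
    unname(oracle$cc_vt30_433), tolerance = 1e-12)
  expect_equal(unname(unlist(
    evaluate_improved(truth_params(80), freq_grid(915e6))[c("eps_real", "eps_loss")])),
    unname(oracle$imp_vt80_915), tolerance = 1e-12)
  sp <- evaluate_improved(truth_params(30), freq_grid(433e6))
  expect_equal(effective_conductivity(sp), oracle$sigma_eff_vt30_433,
               tolerance = 1e-10)
})

test_that("conductivity/loss conversion round-trips to 1e-12 relative", {
  g <- default_grid(51)
  loss <- loss_from_conductivity(rep(0.02, 51), g)
  sp <- dielectric_spectrum(g, rep(50, 51), loss)
  expect_equal(effective_conductivity(sp), rep(0.02, 51), tolerance = 1e-12)
  sp0 <- dielectric_spectrum(g, rep(50, 51), rep(0, 51))
  expect_identical(effective_conductivity(sp0), rep(0, 51))
})

test_that("conduction-dominated loss decreases with frequency", {
  # omega*tau << 1 across the band, relaxation loss negligible vs conduction
  g <- default_grid(41)
  sp <- evaluate_cole_cole(cole_cole_params(3, 1e-4, 1e-13, 0, 0.05), g)
  expect_true(all(diff(sp$eps_loss) < 0))
})

test_that("tabulated parameters give strictly decreasing conductivity at 433 MHz", {
  tab <- tidal_volume_table()
  sig433 <- vapply(tab, function(p) {
    effective_conductivity(evaluate_improved(p, freq_grid(433e6)))
  }, numeric(1L))
  expect_true(all(diff(sig433) < 0))
  # the extreme conditions decrease everywhere in-band, both components
  g <- default_grid()
  lo <- evaluate_improved(tab[["30"]], g)
  hi <- evaluate_improved(tab[["80"]], g)
  expect_true(all(hi$eps_real < lo$eps_real))
  expect_true(all(hi$eps_loss < lo$eps_loss))
})

test_that("unphysical parameter combinations are rejected", {
  # strongly negative linear term drives eps_real below zero at band top
  p <- improved_cole_cole_params(cole_cole_params(2, 1, 1e-12), -1e-8)
  expect_error(evaluate_improved(p, default_grid()), "eps_real <= 0")
})
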