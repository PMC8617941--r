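truth_single_pole <- function() {
  cole_cole_model(4, 0.7, list(cole_pole(50, 8e-12, 0.1)))
}

test_that("noiseless sweep refits to high relative accuracy", {
  truth <- truth_single_pole()
  sweep <- sweep_from_model(truth, study_grid())
  fit <- fit_single_pole(sweep)
  expect_true(fit$converged)
  got <- c(fit$model$eps_inf, fit$model$sigma_s, fit$model$poles[[1]]$delta_eps,
           fit$model$poles[[1]]$tau, fit$model$poles[[1]]$alpha)
  want <- c(4, 0.7, 50, 8e-12, 0.1)
  expect_lt(max(rel_err(got, want)), 1e-6)
})

test_that("constant sweep drives the increment to its lower bound", {
  f <- study_grid()[seq(1, 1581, by = 10)]
  sweep <- frequency_sweep(f, rep(4, length(f)), rep(0, length(f)))
  fit <- fit_single_pole(sweep)
  expect_lt(fit$model$poles[[1]]$delta_eps, 1e-8)
  expect_lt(fit$model$sigma_s, 1e-10)
  expect_lt(fit$residual_norm, 1e-10)
})

test_that("noisy sweeps recover increment and relaxation time within 5%", {
  truth <- truth_single_pole()
  f <- study_grid()
  eps <- evaluate_permittivity(truth, f)
  errs <- sapply(1:20, function(s) {
    set.seed(1000 + s)
    sweep <- frequency_sweep(f, Re(eps) + rnorm(length(f), 0, 0.5),
                             -Im(eps) + rnorm(length(f), 0, 0.5))
    fit <- fit_single_pole(sweep)
    c(de = (fit$model$poles[[1]]$delta_eps - 50) / 50,
      tau = (fit$model$poles[[1]]$tau - 8e-12) / 8e-12)
  })
  expect_true(all(abs(errs) < 0.05))
  expect_lt(abs(median(errs["de", ])), 0.01)
  expect_lt(abs(median(errs["tau", ])), 0.01)
})

test_that("fit is invariant under subsampling the noiseless grid by two", {
  truth <- truth_single_pole()
  f <- study_grid()
  fit1 <- fit_single_pole(sweep_from_model(truth, f))
  fit2 <- fit_single_pole(sweep_from_model(truth, f[seq(1, length(f), by = 2)]))
  p1 <- c(fit1$model$eps_inf, fit1$model$sigma_s, fit1$model$poles[[1]]$delta_eps,
          fit1$model$poles[[1]]$tau, fit1$model$poles[[1]]$alpha)
  p2 <- c(fit2$model$eps_inf, fit2$model$sigma_s, fit2$model$poles[[1]]$delta_eps,
          fit2$model$poles[[1]]$tau, fit2$model$poles[[1]]$alpha)
  expect_lt(max(rel_err(p1, p2)), 1e-6)
})

test_that("fitting is deterministic: repeated calls bit-agree", {
  truth <- truth_single_pole()
  f <- study_grid()
  eps <- evaluate_permittivity(truth, f)
  set.seed(7)
  sweep <- frequency_sweep(f, Re(eps) + rnorm(length(f), 0, 0.5),
                           -Im(eps) + rnorm(length(f), 0, 0.5))
  fit1 <- fit_single_pole(sweep)
  fit2 <- fit_single_pole(sweep)
  expect_identical(unclass(fit1$model), unclass(fit2$model))
  expect_identical(fit1$residual_norm, fit2$residual_norm)
})

test_that("degenerate sweeps are rejected up front", {
  expect_error(frequency_sweep(2.45e9, 50, 10) |> fit_single_pole(), "at least 10")
  f <- study_grid()[1:20]
  sweep <- frequency_sweep(f, rep(50, 20), c(NA, rep(10, 19)))
  expect_error(suppressWarnings(fit_single_pole(sweep)), "NA")
})

test_that("returned parameters respect the bounds", {
  # data pulled well below the eps_inf lower bound
  f <- study_grid()[seq(1, 1581, by = 20)]
  sweep <- frequency_sweep(f, rep(-5, length(f)), rep(0, length(f)))
  fit <- fit_single_pole(sweep)
  b <- default_fit_bounds()
  got <- c(fit$model$eps_inf, fit$model$sigma_s, fit$model$poles[[1]]$delta_eps,
           fit$model$poles[[1]]$tau * 1e12, fit$model$poles[[1]]$alpha)
  expect_true(all(got >= b$lower - 1e-12))
  expect_true(all(got <= b$upper + 1e-12))
})

test_that("exactly linear parameter trends are recovered with R squared 1", {
  temps <- c(20, 25, 30, 35, 37, 40, 43, 45)
  fits <- lapply(temps, function(T) {
    fake_fit(3.7529 - 0.0746 * T, 0.9585 + 0.0393 * T, 59.7534 - 0.1545 * T,
             11.7765 - 0.1243 * T, 0.1646 - 0.0014 * T, temperature = T)
  })
  out <- fit_parameter_polynomials(fits, order = 1)
  want <- list(eps_inf = c(3.7529, -0.0746), sigma_s = c(0.9585, 0.0393),
               delta_eps = c(59.7534, -0.1545), tau = c(11.7765, -0.1243),
               alpha = c(0.1646, -0.0014))
  for (nm in names(want)) {
    expect_lt(max(rel_err(out$polynomials[[nm]]$law$coefficients, want[[nm]])),
              1e-9)
    expect_equal(out$polynomials[[nm]]$r_squared, 1, tolerance = 1e-12)
  }
})

test_that("quadratic laws never fit worse than linear ones", {
  set.seed(99)
  temps <- rep(c(20, 25, 30, 35, 37, 40, 43, 45), each = 3)
  fits <- lapply(temps, function(T) {
    fake_fit(4 + 0.01 * T + rnorm(1, 0, 0.2),
             0.5 + 0.02 * T + rnorm(1, 0, 0.05),
             55 - 0.1 * T + rnorm(1, 0, 0.5),
             11 - 0.1 * T + rnorm(1, 0, 0.2),
             0.12 + rnorm(1, 0, 0.005), temperature = T + rnorm(1, 0, 0.5))
  })
  o1 <- suppressWarnings(fit_parameter_polynomials(fits, order = 1))
  o2 <- suppressWarnings(fit_parameter_polynomials(fits, order = 2))
  for (nm in names(o1$polynomials)) {
    expect_gte(o2$polynomials[[nm]]$r_squared, o1$polynomials[[nm]]$r_squared)
    expect_lte(sum(o2$polynomials[[nm]]$residuals^2),
               sum(o1$polynomials[[nm]]$residuals^2))
  }
})

test_that("too few distinct temperatures is a validation error", {
  fits <- lapply(c(37, 37, 37), function(T) {
    fake_fit(4, 0.7, 50, 8, 0.1, temperature = T)
  })
  expect_error(fit_parameter_polynomials(fits, order = 1), "distinct temperatures")
})

test_that("per-temperature aggregation averages replicate sweeps first", {
  temps <- rep(c(20, 30, 40, 45), each = 2)
  # replicates offset symmetrically: per-temperature means lie exactly on a line
  off <- rep(c(-0.5, 0.5), times = 4)
  fits <- lapply(seq_along(temps), function(i) {
    T <- temps[i]
    fake_fit(4, 0.7, 50 - 0.1 * T + off[i], 8, 0.1, temperature = T)
  })
  out <- fit_parameter_polynomials(fits, order = 1, aggregate = "per_temperature")
  expect_lt(max(rel_err(out$polynomials$delta_eps$law$coefficients,
                        c(50, -0.1))), 1e-9)
})

test_that("campaign RMSE is zero for a truth-generated campaign", {
  tm <- muscle_temperature_model()
  camp <- generate_campaign(
    tm, campaign_design(samples_per_temperature = 1, sites_per_sample = 1,
                        f_step = 0.5e9, seed = 5),
    confounder_config(temp_jitter_sd = 0, noise_sd_re = 0, noise_sd_im = 0,
                      pressure_mean_kPa = 15, pressure_sd_kPa = 0))
  expect_lt(model_rmse(tm, camp), 1e-12)
})

test_that("campaign RMSE recovers a known noise scale", {
  tm <- muscle_temperature_model()
  camp <- generate_campaign(
    tm, campaign_design(seed = 8),
    confounder_config(temp_jitter_sd = 0, noise_sd_re = 0.5, noise_sd_im = 0.5,
                      pressure_mean_kPa = 15, pressure_sd_kPa = 0))
  # 72 x 1581 x 2 pooled residuals
  expect_equal(model_rmse(tm, camp), 0.5, tolerance = 0.02)
})

test_that("empty campaigns are rejected by the RMSE stage", {
  tm <- muscle_temperature_model()
  expect_error(model_rmse(tm, measurement_campaign(list())), "empty")
})

test_that("model comparison tabulates identical models identically", {
  g <- literature_models()$Gabriel
  f <- exp(seq(log(0.5e9), log(40e9), length.out = 50))
  tab <- compare_models(list(a = g, b = g), f)
  expect_identical(tab$eps_real[tab$label == "a"], tab$eps_real[tab$label == "b"])
  expect_identical(tab$eps_imag[tab$label == "a"], tab$eps_imag[tab$label == "b"])
  # single-frequency grid: one row per model
  tab1 <- compare_models(list(a = g, b = g), 2.45e9)
  expect_identical(nrow(tab1), 2L)
})

test_that("comparison summary reports pairwise differences vs the baseline", {
  reg <- literature_models()
  f <- exp(seq(log(0.5e9), log(40e9), length.out = 100))
  s <- compare_summary(reg[c("Gabriel", "Peyman", "Abdilla")], f)
  expect_identical(nrow(s), 2L)
  expect_true(all(s$max_abs_d_eps_real >= s$mean_abs_d_eps_real))
})
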