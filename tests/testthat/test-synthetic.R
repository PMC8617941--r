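quiet_design <- function(...) {
  confounder_config(temp_jitter_sd = 0, noise_sd_re = 0, noise_sd_im = 0,
                    pressure_mean_kPa = 15, pressure_sd_kPa = 0, ...)
}

test_that("the noise-free limit reproduces the truth model exactly", {
  tm <- muscle_temperature_model()
  d <- campaign_design(samples_per_temperature = 1, sites_per_sample = 1,
                       f_step = 0.5e9, seed = 2)
  camp <- generate_campaign(tm, d, quiet_design())
  for (s in camp$sweeps) {
    m <- model_at_temperature(tm, s$set_temperature)
    eps <- evaluate_permittivity(m, s$frequencies)
    expect_identical(s$actual_temperature, s$set_temperature)
    expect_equal(s$eps_real, Re(eps), tolerance = 1e-14)
    expect_equal(s$eps_imag, -Im(eps), tolerance = 1e-14)
  }
})

test_that("the default design yields 72 sweeps of 1581 points", {
  tm <- muscle_temperature_model()
  camp <- generate_campaign(tm, campaign_design(seed = 1), confounder_config())
  expect_length(camp$sweeps, 72L)
  expect_true(all(vapply(camp$sweeps, function(s) length(s$frequencies),
                         integer(1)) == 1581L))
  expect_true(is_synthetic(camp))
  expect_identical(nrow(camp$environment_log), 72L)
})

test_that("identical seeds reproduce campaigns bit-identically", {
  tm <- muscle_temperature_model()
  d <- campaign_design(set_temperatures = c(20, 37, 45), f_step = 1e9, seed = 77)
  c1 <- generate_campaign(tm, d, confounder_config())
  c2 <- generate_campaign(tm, d, confounder_config())
  expect_identical(lapply(c1$sweeps, unclass), lapply(c2$sweeps, unclass))
  expect_identical(c1$environment_log, c2$environment_log)
})

test_that("the delta tail lifts the low end and barely moves the high end", {
  tm <- muscle_temperature_model()
  d <- campaign_design(samples_per_temperature = 1, sites_per_sample = 1,
                       seed = 4)
  base <- generate_campaign(tm, d, quiet_design())
  tail <- generate_campaign(tm, d, quiet_design(delta_tail = default_delta_tail()))
  for (i in seq_along(base$sweeps)) {
    f <- base$sweeps[[i]]$frequencies
    d_re <- tail$sweeps[[i]]$eps_real - base$sweeps[[i]]$eps_real
    expect_gt(d_re[1], 0)            # lifted at 0.5 GHz
    expect_lt(d_re[length(f)], 10)   # under 10 permittivity units at 40 GHz
    expect_gt(d_re[1], d_re[length(f)])
  }
})

test_that("a neutral pressure draw equals a zero pressure sensitivity", {
  tm <- muscle_temperature_model()
  d <- campaign_design(set_temperatures = c(25, 40), f_step = 1e9, seed = 10)
  c1 <- generate_campaign(tm, d, confounder_config(pressure_mean_kPa = 15,
                                                   pressure_sd_kPa = 0))
  c2 <- generate_campaign(tm, d, confounder_config(pressure_mean_kPa = 15,
                                                   pressure_sd_kPa = 0,
                                                   pressure_sensitivity = 0))
  expect_identical(lapply(c1$sweeps, `[[`, "eps_real"),
                   lapply(c2$sweeps, `[[`, "eps_real"))
})

test_that("pressure sensitivity scales both permittivity parts", {
  tm <- muscle_temperature_model()
  d <- campaign_design(set_temperatures = 37, samples_per_temperature = 1,
                       sites_per_sample = 1, f_step = 1e9, seed = 11)
  base <- generate_campaign(tm, d, quiet_design())
  # pressure fixed 1 kPa above setpoint with -0.3%/kPa sensitivity
  shifted <- generate_campaign(
    tm, d, confounder_config(temp_jitter_sd = 0, noise_sd_re = 0,
                             noise_sd_im = 0, pressure_mean_kPa = 16,
                             pressure_sd_kPa = 0))
  fac <- 1 - 0.003
  expect_equal(shifted$sweeps[[1]]$eps_real, base$sweeps[[1]]$eps_real * fac,
               tolerance = 1e-12)
  expect_equal(shifted$sweeps[[1]]$eps_imag, base$sweeps[[1]]$eps_imag * fac,
               tolerance = 1e-12)
})

test_that("weight loss obeys the two dehydration regimes", {
  tm <- muscle_temperature_model()
  camp <- generate_campaign(tm, campaign_design(f_step = 2e9, seed = 13),
                            confounder_config())
  loss <- vapply(camp$sweeps, function(s) {
    1 - s$weight_after / s$weight_before
  }, numeric(1))
  setT <- vapply(camp$sweeps, `[[`, numeric(1), "set_temperature")
  expect_true(all(loss[setT <= 40] < 0.01))
  expect_true(all(loss[setT > 40] <= 0.06))
  expect_true(all(loss >= 0))
})

test_that("noise-free validation sweeps reproduce the reference exactly", {
  ref <- literature_models()$Peyman
  grid <- seq(1e9, 1e10, by = 2.5e8)
  vp <- generate_validation_sweeps(ref, n_pre = 1, n_post = 1, noise_sd = 0,
                                   drift_offset = 0, frequencies = grid, seed = 1)
  eps <- evaluate_permittivity(ref, grid)
  expect_equal(vp$pre_sweeps[[1]]$eps_real, Re(eps), tolerance = 1e-14)
  expect_equal(vp$post_sweeps[[1]]$eps_imag, -Im(eps), tolerance = 1e-14)
})

test_that("confounder-free end-to-end recovery is exact to optimizer tolerance", {
  tm <- muscle_temperature_model()
  d <- campaign_design(samples_per_temperature = 1, sites_per_sample = 1,
                       seed = 3)
  rep <- end_to_end_recovery(tm, d, quiet_design(), order = 1)
  expect_lt(max(abs(unlist(rep$coef_rel_error))), 1e-6)
  expect_lt(rep$rmse, 1e-8)
  expect_identical(rep$rmse_truth, 0)
})

test_that("recovery error does not improve as noise grows", {
  tm <- muscle_temperature_model()
  d <- campaign_design(samples_per_temperature = 1, sites_per_sample = 1,
                       f_step = 0.25e9, seed = 21)
  med_err <- vapply(c(0, 0.5, 2), function(ns) {
    cf <- confounder_config(temp_jitter_sd = 0, noise_sd_re = ns,
                            noise_sd_im = ns, pressure_mean_kPa = 15,
                            pressure_sd_kPa = 0)
    rep <- end_to_end_recovery(tm, d, cf, order = 1)
    median(abs(as.matrix(rep$sweep_param_rel_error[, 1:5])))
  }, numeric(1))
  expect_true(all(diff(med_err) >= 0))
})

test_that("campaign directories round-trip losslessly", {
  tm <- muscle_temperature_model()
  d <- campaign_design(set_temperatures = c(20, 45), f_step = 2e9, seed = 31)
  camp <- generate_campaign(tm, d, confounder_config())
  camp$validation <- generate_validation_sweeps(
    literature_models()$Peyman, n_pre = 2, n_post = 2, noise_sd = 0.1,
    frequencies = seq(1e9, 1e10, 1e9), seed = 32)
  dir <- withr::local_tempdir()
  path <- file.path(dir, "campaign")
  write_campaign(camp, path)
  back <- read_campaign(path)
  expect_length(back$sweeps, length(camp$sweeps))
  for (i in seq_along(camp$sweeps)) {
    expect_identical(back$sweeps[[i]]$frequencies, camp$sweeps[[i]]$frequencies)
    expect_identical(back$sweeps[[i]]$eps_real, camp$sweeps[[i]]$eps_real)
    expect_identical(back$sweeps[[i]]$eps_imag, camp$sweeps[[i]]$eps_imag)
    expect_identical(back$sweeps[[i]]$actual_temperature,
                     camp$sweeps[[i]]$actual_temperature)
    expect_identical(back$sweeps[[i]]$contact_pressure,
                     camp$sweeps[[i]]$contact_pressure)
  }
  expect_true(is_synthetic(back))
  for (nm in names(tm$laws)) {
    expect_identical(back$truth$laws[[nm]]$coefficients, tm$laws[[nm]]$coefficients)
  }
  expect_length(back$validation$pre_sweeps, 2L)
  expect_identical(back$validation$pre_sweeps[[1]]$eps_real,
                   camp$validation$pre_sweeps[[1]]$eps_real)
  # refusing to clobber without overwrite
  expect_error(write_campaign(camp, path), "exists")
  expect_silent(write_campaign(camp, path, overwrite = TRUE))
})
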