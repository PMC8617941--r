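#' @title Synthetic measurement-campaign generator
#' @name synthetic
#' @description Generates dielectric measurement campaigns with the
#'   statistical structure of a controlled open-ended coaxial probe study:
#'   a fixed set-temperature design with several samples and probing sites
#'   per temperature, a dense microwave frequency grid, jitter between set
#'   and actual sample temperature, additive complex Gaussian noise, and
#'   optional confounders (an unmodelled slow delta-dispersion tail,
#'   contact-pressure sensitivity, dehydration monitoring).
NULL

#' Campaign design: temperatures, replication and frequency grid
#'
#' Defaults mirror the reference study design: 8 set temperatures (20, 25,
#' 30, 35, 37, 40, 43, 45 degC), 3 samples times 3 probing sites per
#' temperature (72 sweeps in total) and a 0.5-40 GHz grid in 25 MHz steps
#' (1581 points).
#'
#' @param set_temperatures Water-bath set temperatures in degrees Celsius.
#' @param samples_per_temperature,sites_per_sample Replication counts.
#' @param f_start,f_stop,f_step Frequency grid in Hz.
#' @param seed Integer seed; the campaign is bit-reproducible from it.
#' @return A list of class `campaign_design`.
#' @export
campaign_design <- function(set_temperatures = c(20, 25, 30, 35, 37, 40, 43, 45),
                            samples_per_temperature = 3L,
                            sites_per_sample = 3L,
                            f_start = 0.5e9, f_stop = 40e9, f_step = 25e6,
                            seed = 1L) {
  stopifnot(length(set_temperatures) >= 1L,
            samples_per_temperature >= 1L, sites_per_sample >= 1L,
            f_start > 0, f_step > 0, f_stop > f_start)
  structure(
    list(set_temperatures = as.numeric(set_temperatures),
         samples_per_temperature = as.integer(samples_per_temperature),
         sites_per_sample = as.integer(sites_per_sample),
         f_start = f_start, f_stop = f_stop, f_step = f_step,
         seed = as.integer(seed)),
    class = "campaign_design"
  )
}

#' Confounder configuration for synthetic campaigns
#'
#' Defaults reproduce the monitored statistics of the reference study:
#' contact pressure 14.6 +/- 0.61 kPa around a 15 kPa setpoint with a -0.3%
#' permittivity change per kPa, room humidity 71.4 +/- 0.9%, room
#' temperature 20.6 +/- 0.4 degC, relative weight loss below 1% up to
#' 40 degC and up to 6% above it. Temperature jitter (0.5 degC) and the
#' additive noise scales (0.5 on each permittivity part) are generator
#' defaults at the order of magnitude of reported measurement scatter, not
#' published values.
#'
#' @param temp_jitter_sd Std. dev. (degC) of actual around set temperature.
#' @param noise_sd_re,noise_sd_im Additive Gaussian noise scales on the real
#'   and imaginary permittivity parts.
#' @param delta_tail Optional [cole_pole()] added to the truth model to
#'   emulate an unmodelled slow dispersion; `NULL` (default) disables it.
#'   See [default_delta_tail()].
#' @param pressure_mean_kPa,pressure_sd_kPa Per-sweep contact-pressure draw.
#' @param pressure_sensitivity Relative permittivity change per kPa of
#'   deviation from the 15 kPa setpoint, applied multiplicatively to both
#'   parts.
#' @param humidity_mean,humidity_sd Room humidity (%) log entries.
#' @param room_temp_mean,room_temp_sd Room temperature (degC) log entries.
#' @param dehydration_max_low,dehydration_max_high Upper bounds of the
#'   uniform relative weight-loss draw for set temperatures up to / above
#'   `dehydration_threshold` degC.
#' @param dehydration_threshold Set temperature (degC) separating the two
#'   weight-loss regimes.
#' @param dehydration_eps_coupling Relative permittivity change per unit
#'   weight-loss fraction; 0 (default) keeps dehydration a monitoring
#'   variable that never perturbs the permittivity.
#' @return A list of class `confounder_config`.
#' @export
confounder_config <- function(temp_jitter_sd = 0.5,
                              noise_sd_re = 0.5, noise_sd_im = 0.5,
                              delta_tail = NULL,
                              pressure_mean_kPa = 14.6, pressure_sd_kPa = 0.61,
                              pressure_sensitivity = -0.003,
                              humidity_mean = 71.4, humidity_sd = 0.9,
                              room_temp_mean = 20.6, room_temp_sd = 0.4,
                              dehydration_max_low = 0.01,
                              dehydration_max_high = 0.06,
                              dehydration_threshold = 40,
                              dehydration_eps_coupling = 0) {
  stopifnot(temp_jitter_sd >= 0, noise_sd_re >= 0, noise_sd_im >= 0,
            pressure_sd_kPa >= 0, humidity_sd >= 0, room_temp_sd >= 0,
            dehydration_max_low >= 0, dehydration_max_high >= 0)
  if (!is.null(delta_tail)) stopifnot(inherits(delta_tail, "cole_pole"))
  structure(
    list(temp_jitter_sd = temp_jitter_sd,
         noise_sd_re = noise_sd_re, noise_sd_im = noise_sd_im,
         delta_tail = delta_tail,
         pressure_mean_kPa = pressure_mean_kPa,
         pressure_sd_kPa = pressure_sd_kPa,
         pressure_sensitivity = pressure_sensitivity,
         humidity_mean = humidity_mean, humidity_sd = humidity_sd,
         room_temp_mean = room_temp_mean, room_temp_sd = room_temp_sd,
         dehydration_max_low = dehydration_max_low,
         dehydration_max_high = dehydration_max_high,
         dehydration_threshold = dehydration_threshold,
         dehydration_eps_coupling = dehydration_eps_coupling),
    class = "confounder_config"
  )
}

#' The default slow delta-dispersion tail pole
#'
#' The literature two-pole muscle model's slow dispersion
#' (delta_eps = 7000, tau = 353.68 ns, alpha = 0.10; relaxation frequency
#' 0.45 MHz). Added to a synthetic truth model it reproduces the
#' misspecification situation of fitting a single gamma pole to data whose
#' low-frequency end carries the tail of an unmodelled dispersion.
#'
#' @return A [cole_pole()].
#' @export
default_delta_tail <- function() cole_pole(7000, 353.68e-9, 0.10)

design_frequencies <- function(design) {
  seq(design$f_start, design$f_stop, by = design$f_step)
}

#' Generate a synthetic measurement campaign
#'
#' For each (set temperature, sample, site) triple: draws the actual sample
#' temperature around the set one, evaluates the truth model (plus an
#' optional delta-dispersion tail) at that temperature on the design grid,
#' applies the multiplicative contact-pressure effect
#' `1 + pressure_sensitivity * (pressure - 15 kPa)`, and adds independent
#' Gaussian noise to both permittivity parts. Sample weights before/after
#' and an environment log (humidity, room temperature) are drawn to emulate
#' campaign metadata. Fully reproducible from `design$seed`.
#'
#' Temperature jitter may place an actual temperature slightly outside the
#' truth model's stated validity range; the polynomial laws are then
#' extrapolated, which is smooth and intentional.
#'
#' @param truth A [temperature_model()] generating the data; it is recorded
#'   on the returned campaign.
#' @param design A [campaign_design()].
#' @param confounders A [confounder_config()].
#' @return A synthetic [measurement_campaign()].
#' @examples
#' tm <- muscle_temperature_model()
#' camp <- generate_campaign(tm, campaign_design(set_temperatures = c(20, 45),
#'                                               f_step = 1e9, seed = 7),
#'                           confounder_config())
#' length(camp$sweeps) # 2 temperatures x 3 samples x 3 sites
#' @export
generate_campaign <- function(truth, design = campaign_design(),
                              confounders = confounder_config()) {
  stopifnot(inherits(truth, "temperature_model"),
            inherits(design, "campaign_design"),
            inherits(confounders, "confounder_config"))
  set.seed(design$seed)
  f <- design_frequencies(design)
  cf <- confounders
  sweeps <- list()
  env <- list()
  k <- 0L
  for (setT in design$set_temperatures) {
    for (sample_id in seq_len(design$samples_per_temperature)) {
      weight_before <- stats::rnorm(1, 8.5, 0.3) # ~2 cm cube of muscle, grams
      loss_max <- if (setT <= cf$dehydration_threshold) {
        cf$dehydration_max_low
      } else {
        cf$dehydration_max_high
      }
      loss <- stats::runif(1, 0, loss_max)
      for (site_id in seq_len(design$sites_per_sample)) {
        k <- k + 1L
        actualT <- stats::rnorm(1, setT, cf$temp_jitter_sd)
        m <- suppressWarnings(model_at_temperature(truth, actualT, strict = FALSE))
        if (!is.null(cf$delta_tail)) {
          m$poles <- c(m$poles, list(cf$delta_tail))
        }
        eps <- evaluate_permittivity(m, f)
        er <- Re(eps); ei <- -Im(eps)
        pressure <- stats::rnorm(1, cf$pressure_mean_kPa, cf$pressure_sd_kPa)
        fac <- 1 + cf$pressure_sensitivity * (pressure - 15)
        if (cf$dehydration_eps_coupling != 0) {
          fac <- fac * (1 + cf$dehydration_eps_coupling * loss)
        }
        er <- er * fac; ei <- ei * fac
        er <- er + stats::rnorm(length(f), 0, cf$noise_sd_re)
        ei <- ei + stats::rnorm(length(f), 0, cf$noise_sd_im)
        sweeps[[k]] <- frequency_sweep(
          f, er, ei,
          actual_temperature = actualT, set_temperature = setT,
          sample_id = sample_id, site_id = site_id,
          contact_pressure = pressure,
          weight_before = weight_before,
          weight_after = weight_before * (1 - loss)
        )
        env[[k]] <- data.frame(
          sweep = k, set_temperature = setT,
          humidity = stats::rnorm(1, cf$humidity_mean, cf$humidity_sd),
          room_temperature = stats::rnorm(1, cf$room_temp_mean, cf$room_temp_sd)
        )
      }
    }
  }
  measurement_campaign(
    sweeps, environment_log = do.call(rbind, env), truth = truth,
    design = unclass(design),
    confounders = confounder_to_list(cf)
  )
}

confounder_to_list <- function(cf) {
  out <- unclass(cf)
  if (!is.null(out$delta_tail)) out$delta_tail <- unclass(out$delta_tail)
  out
}

#' Generate pre/post validation sweeps on a reference liquid
#'
#' Pre sweeps are the reference model plus noise; post sweeps additionally
#' carry a constant drift offset, emulating calibration drift over a
#' measurement run.
#'
#' @param reference A [cole_cole_model()] for the reference liquid.
#' @param n_pre,n_post Sweep counts (>= 1 each).
#' @param noise_sd Additive Gaussian noise scale; scalar (both parts) or
#'   length 2 `(real, imag)`.
#' @param drift_offset Constant offset added to the post sweeps; scalar
#'   (real part only) or length 2 `(real, imag)`.
#' @param frequencies Frequency grid in Hz.
#' @param seed Integer seed.
#' @return A [validation_pair()].
#' @export
generate_validation_sweeps <- function(reference, n_pre = 1L, n_post = 1L,
                                       noise_sd = 0, drift_offset = 0,
                                       frequencies = seq(0.5e9, 40e9, by = 25e6),
                                       seed = 1L) {
  stopifnot(inherits(reference, "cole_cole_model"), n_pre >= 1L, n_post >= 1L)
  noise_sd <- rep_len(as.numeric(noise_sd), 2L)
  drift <- if (length(drift_offset) == 1L) c(drift_offset, 0) else
    as.numeric(drift_offset)[1:2]
  set.seed(seed)
  eps <- evaluate_permittivity(reference, frequencies)
  er <- Re(eps); ei <- -Im(eps)
  mk <- function(offset) {
    frequency_sweep(
      frequencies,
      er + offset[1] + stats::rnorm(length(frequencies), 0, noise_sd[1]),
      ei + offset[2] + stats::rnorm(length(frequencies), 0, noise_sd[2])
    )
  }
  pre <- lapply(seq_len(n_pre), function(i) mk(c(0, 0)))
  post <- lapply(seq_len(n_post), function(i) mk(drift))
  validation_pair(pre, post, reference)
}

#' End-to-end recovery harness: generate, fit, refit laws, score
#'
#' Runs the full pipeline on a synthetic campaign — [generate_campaign()],
#' [fit_single_pole()] per sweep, [fit_parameter_polynomials()],
#' [model_rmse()] — and reports how well the known truth is recovered.
#'
#' @param truth A [temperature_model()].
#' @param design A [campaign_design()].
#' @param confounders A [confounder_config()].
#' @param order Polynomial order of the refitted laws (1 or 2).
#' @param aggregate Passed to [fit_parameter_polynomials()].
#' @return An object of class `recovery_report`: the campaign, per-sweep
#'   fits, the refitted `tmodel` with per-parameter `r_squared`, campaign
#'   RMSEs of both the refitted and the truth model, per-law coefficient
#'   relative errors (when the truth law has the same order), and a
#'   data.frame of per-sweep parameter relative errors against the truth
#'   evaluated at each sweep's actual temperature.
#' @export
end_to_end_recovery <- function(truth, design = campaign_design(),
                                confounders = confounder_config(),
                                order = 1, aggregate = "per_sweep") {
  campaign <- generate_campaign(truth, design, confounders)
  fits <- lapply(campaign$sweeps, fit_single_pole)
  poly <- fit_parameter_polynomials(fits, order = order, aggregate = aggregate,
                                    label = "recovered laws")
  rmse_fit <- suppressWarnings(model_rmse(poly$tmodel, campaign))
  rmse_truth <- suppressWarnings(model_rmse(truth, campaign))

  coef_rel_error <- lapply(LAW_NAMES, function(nm) {
    tl <- truth$laws[[nm]]; fl <- poly$polynomials[[nm]]$law
    if (tl$order != fl$order) return(rep(NA_real_, fl$order + 1L))
    (fl$coefficients - tl$coefficients) / tl$coefficients
  })
  names(coef_rel_error) <- LAW_NAMES

  sweep_err <- do.call(rbind, lapply(seq_along(fits), function(i) {
    f <- fits[[i]]
    tm <- suppressWarnings(
      model_at_temperature(truth, f$actual_temperature, strict = FALSE))
    tp <- c(tm$eps_inf, tm$sigma_s, tm$poles[[1]]$delta_eps,
            tm$poles[[1]]$tau * 1e12, tm$poles[[1]]$alpha)
    fp <- c(f$model$eps_inf, f$model$sigma_s, f$model$poles[[1]]$delta_eps,
            f$model$poles[[1]]$tau * 1e12, f$model$poles[[1]]$alpha)
    out <- as.data.frame(as.list((fp - tp) / tp))
    names(out) <- LAW_NAMES
    out$actual_temperature <- f$actual_temperature
    out
  }))

  structure(
    list(campaign = campaign, fits = fits, polynomials = poly$polynomials,
         tmodel = poly$tmodel,
         r_squared = vapply(poly$polynomials, `[[`, numeric(1), "r_squared"),
         rmse = rmse_fit, rmse_truth = rmse_truth,
         coef_rel_error = coef_rel_error,
         sweep_param_rel_error = sweep_err,
         order = order),
    class = "recovery_report"
  )
}

#' @export
print.recovery_report <- function(x, ...) {
  cat(sprintf("End-to-end recovery (order-%d laws, %d sweeps)\n",
              x$order, length(x$fits)))
  cat(sprintf("  campaign RMSE: refit %.4g, truth %.4g\n", x$rmse, x$rmse_truth))
  med <- vapply(LAW_NAMES, function(nm) {
    stats::median(x$sweep_param_rel_error[[nm]])
  }, numeric(1))
  cat("  median per-sweep relative bias:\n")
  for (nm in LAW_NAMES) cat(sprintf("    %-9s %+.3g%%\n", nm, 100 * med[[nm]]))
  invisible(x)
}
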