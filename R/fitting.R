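#' @title Cole-Cole model fitting
#' @name fitting
#' @description Two-stage inference for temperature-dependent dielectric
#'   models: bounded Levenberg-Marquardt fits of a single-pole Cole-Cole
#'   model to each complex permittivity sweep, then ordinary least-squares
#'   polynomial laws for each parameter against the recorded sample
#'   temperature.
NULL

#' Default parameter bounds for single-pole fits
#'
#' Generous envelopes around the published muscle models: `eps_inf` in
#' `[0, 20]`, `sigma_s` in `[0, 10]` S/m, `delta_eps` in `[0, 200]`, `tau` in
#' `[0.1, 100]` ps, `alpha` in `[0, 0.5]`.
#'
#' @return Named list with `lower` and `upper` numeric vectors over
#'   `(eps_inf, sigma_s, delta_eps, tau_ps, alpha)`.
#' @export
default_fit_bounds <- function() {
  list(lower = c(eps_inf = 0, sigma_s = 0, delta_eps = 0, tau_ps = 0.1, alpha = 0),
       upper = c(eps_inf = 20, sigma_s = 10, delta_eps = 200, tau_ps = 100, alpha = 0.5))
}

# parameter vector v = (eps_inf, sigma_s, delta_eps, tau_ps, alpha
#                       [, delta_eps2, tau2_ns, alpha2]) at angular freq w
eval_param_vector <- function(v, w) {
  eps <- v[1] + v[3] / (1 + (1i * w * v[4] * 1e-12)^(1 - v[5])) +
    v[2] / (1i * w * EPS0)
  if (length(v) == 8L) {
    eps <- eps + v[6] / (1 + (1i * w * v[7] * 1e-9)^(1 - v[8]))
  }
  eps
}

#' Fit a single-pole Cole-Cole model to one permittivity sweep
#'
#' Minimizes the stacked residual of real and imaginary parts with equal unit
#' weight, \eqn{[\epsilon'_{model} - \epsilon'_{data},\;
#' \epsilon''_{model} - \epsilon''_{data}]}, over the five parameters
#' (eps_inf, sigma_s, delta_eps, tau, alpha) using bounded
#' Levenberg-Marquardt least squares. Internally the relaxation time is
#' optimized in picoseconds so the Jacobian columns are comparably scaled;
#' the returned model stores tau in seconds.
#'
#' Non-convergence within the evaluation budget is flagged in the result, not
#' raised as an error.
#'
#' @param sweep A [frequency_sweep()] with at least 10 frequency points.
#' @param init Optional starting [cole_cole_model()] (single pole). The
#'   default start is the literature gamma-dispersion point
#'   (eps_inf = 4, sigma_s = 0.2, delta_eps = 50, tau = 7.23 ps, alpha = 0.1).
#' @param bounds Optional list with `lower`/`upper` vectors as in
#'   [default_fit_bounds()].
#' @param two_pole If `TRUE`, additionally fits a slow second pole
#'   (delta_eps2, tau2 in ns, alpha2). Off by default: within a
#'   0.5-40 GHz band a second low-frequency dispersion is numerically
#'   ill-determined, and the flag exists for misspecification experiments
#'   only.
#' @param control A [minpack.lm::nls.lm.control()] list; defaults to
#'   `ftol = ptol = 1e-10`, `maxfev = 5000`.
#' @return An object of class `fit_result`: fields `model`
#'   ([cole_cole_model()]), `residual_norm` (final cost: sum of squares of
#'   the stacked residual), `n_iterations`, `converged`, `covariance_proxy`
#'   (Jacobian-based dispersion estimate, may be `NULL`), and
#'   `actual_temperature` carried from the sweep.
#' @export
fit_single_pole <- function(sweep, init = NULL, bounds = NULL,
                            two_pole = FALSE, control = NULL) {
  stopifnot(inherits(sweep, "frequency_sweep"))
  n <- length(sweep$frequencies)
  if (n < 10L) {
    stop("sweep has ", n, " frequency points; need at least 10", call. = FALSE)
  }
  if (max(sweep$frequencies) / min(sweep$frequencies) < 10) {
    warning("frequency grid spans less than one decade; fit may be ill-determined",
            call. = FALSE)
  }
  if (anyNA(sweep$eps_real) || anyNA(sweep$eps_imag)) {
    stop("sweep contains NA permittivity values", call. = FALSE)
  }
  b <- bounds %||% default_fit_bounds()
  stopifnot(length(b$lower) == 5L, length(b$upper) == 5L)
  v0 <- c(eps_inf = 4, sigma_s = 0.2, delta_eps = 50, tau_ps = 7.23, alpha = 0.1)
  if (!is.null(init)) {
    stopifnot(inherits(init, "cole_cole_model"), length(init$poles) == 1L)
    p <- init$poles[[1]]
    v0 <- c(eps_inf = init$eps_inf, sigma_s = init$sigma_s,
            delta_eps = p$delta_eps, tau_ps = p$tau * 1e12, alpha = p$alpha)
  }
  lower <- b$lower; upper <- b$upper
  if (two_pole) {
    v0 <- c(v0, delta_eps2 = 5000, tau2_ns = 300, alpha2 = 0.1)
    lower <- c(lower, delta_eps2 = 0, tau2_ns = 1, alpha2 = 0)
    upper <- c(upper, delta_eps2 = 2e4, tau2_ns = 1e4, alpha2 = 0.5)
  }
  v0 <- pmin(pmax(v0, lower), upper)
  w <- 2 * pi * sweep$frequencies
  er <- sweep$eps_real
  ei <- sweep$eps_imag
  fn <- function(v) {
    m <- eval_param_vector(v, w)
    c(Re(m) - er, -Im(m) - ei)
  }
  ctrl <- do.call(minpack.lm::nls.lm.control,
                  control %||% list(ftol = 1e-10, ptol = 1e-10, maxfev = 5000))
  fit <- minpack.lm::nls.lm(par = v0, lower = lower, upper = upper,
                            fn = fn, control = ctrl)
  v <- fit$par
  poles <- list(cole_pole(max(v[["delta_eps"]], .Machine$double.xmin),
                          v[["tau_ps"]] * 1e-12, v[["alpha"]]))
  if (two_pole) {
    poles <- c(poles, list(cole_pole(max(v[["delta_eps2"]], .Machine$double.xmin),
                                     v[["tau2_ns"]] * 1e-9, v[["alpha2"]])))
  }
  model <- cole_cole_model(v[["eps_inf"]], v[["sigma_s"]], poles,
                           label = "fitted")
  covar <- tryCatch({
    dof <- max(2L * n - length(v), 1L)
    s2 <- fit$deviance / dof
    s2 * chol2inv(chol(fit$hessian))
  }, error = function(e) NULL)
  structure(
    list(model = model,
         residual_norm = fit$deviance,
         n_iterations = fit$niter,
         converged = fit$info %in% 1:4,
         covariance_proxy = covar,
         actual_temperature = sweep$actual_temperature),
    class = "fit_result"
  )
}

#' @export
print.fit_result <- function(x, ...) {
  cat(sprintf("Single-sweep Cole-Cole fit (%s, %d iterations, cost = %.3g)\n",
              if (x$converged) "converged" else "NOT converged",
              x$n_iterations, x$residual_norm))
  print(x$model)
  invisible(x)
}

fit_params_table <- function(fits) {
  stopifnot(length(fits) >= 1L)
  do.call(rbind, lapply(fits, function(f) {
    p <- f$model$poles[[1]]
    data.frame(actual_temperature = f$actual_temperature,
               eps_inf = f$model$eps_inf, sigma_s = f$model$sigma_s,
               delta_eps = p$delta_eps, tau = p$tau * 1e12, # picoseconds
               alpha = p$alpha, converged = f$converged,
               residual_norm = f$residual_norm)
  }))
}

#' Fit polynomial temperature laws to per-sweep Cole-Cole parameters
#'
#' Second inference stage: each of the five Cole-Cole parameters from the
#' per-sweep fits is regressed on the recorded sample temperature (the
#' temperature at the moment of measurement, not the set temperature) with an
#' ordinary least-squares polynomial of the requested order. The `tau` law is
#' fitted in picoseconds.
#'
#' @param fits List of `fit_result` objects carrying actual temperatures.
#' @param order Polynomial order, 1 or 2.
#' @param aggregate `"per_sweep"` (default) regresses on every sweep's
#'   parameters; `"per_temperature"` first averages parameters within each
#'   distinct temperature.
#' @param temp_range Validity range recorded on the fitted laws; defaults to
#'   the span of the observed temperatures.
#' @param label Label for the returned model.
#' @return A list with `tmodel` (a [temperature_model()]) and `polynomials`,
#'   a named list of per-parameter results with fields `law`, `r_squared`
#'   and `residuals`.
#' @export
fit_parameter_polynomials <- function(fits, order = 1,
                                      aggregate = c("per_sweep", "per_temperature"),
                                      temp_range = NULL, label = "fitted laws") {
  stopifnot(order %in% c(1, 2))
  aggregate <- match.arg(aggregate)
  tab <- fit_params_table(fits)
  if (anyNA(tab$actual_temperature)) {
    stop("every fit must carry an actual temperature", call. = FALSE)
  }
  if (aggregate == "per_temperature") {
    tab <- stats::aggregate(tab[LAW_NAMES], by = list(actual_temperature = tab$actual_temperature), FUN = mean)
  }
  if (length(unique(tab$actual_temperature)) < order + 2) {
    stop("need at least ", order + 2, " distinct temperatures for an order-",
         order, " law", call. = FALSE)
  }
  temp_range <- temp_range %||% range(tab$actual_temperature)
  tt <- tab$actual_temperature
  X <- outer(tt, 0:order, `^`)
  polynomials <- lapply(LAW_NAMES, function(nm) {
    y <- tab[[nm]]
    beta <- stats::lm.fit(X, y)$coefficients
    fitted <- drop(X %*% beta)
    res <- y - fitted
    ss_res <- sum(res^2)
    ss_tot <- sum((y - mean(y))^2)
    r2 <- if (ss_tot > 0) 1 - ss_res / ss_tot else as.numeric(ss_res <= 1e-20)
    law_name <- if (nm == "tau") "tau" else nm
    law <- temperature_law(law_name, unname(beta), temp_range = temp_range,
                           on_invalid = "warn")
    list(law = law, r_squared = r2, residuals = res)
  })
  names(polynomials) <- LAW_NAMES
  tmodel <- temperature_model(lapply(polynomials, `[[`, "law"), label = label)
  list(tmodel = tmodel, polynomials = polynomials)
}


#' Campaign-level RMSE of a temperature model
#'
#' Root mean square error over the pooled set of real-part and
#' imaginary-part residuals across all frequencies of all sweeps, with equal
#' weight for the two parts. Sweeps whose recorded temperature falls outside
#' the model's validity range are evaluated by extrapolation with a single
#' summary warning.
#'
#' @param tmodel A [temperature_model()].
#' @param campaign A [measurement_campaign()] with at least one sweep.
#' @return Scalar RMSE in permittivity units.
#' @export
model_rmse <- function(tmodel, campaign) {
  stopifnot(inherits(tmodel, "temperature_model"),
            inherits(campaign, "measurement_campaign"))
  if (length(campaign$sweeps) == 0L) stop("empty campaign", call. = FALSE)
  temps <- vapply(campaign$sweeps, `[[`, numeric(1), "actual_temperature")
  if (anyNA(temps)) stop("every sweep needs an actual temperature", call. = FALSE)
  outside <- temps < tmodel$temp_range[1] | temps > tmodel$temp_range[2]
  if (any(outside)) {
    warning(sum(outside), " sweep temperature(s) outside the model validity ",
            "range; extrapolating", call. = FALSE)
  }
  ss <- 0; nn <- 0L
  for (s in campaign$sweeps) {
    m <- suppressWarnings(model_at_temperature(tmodel, s$actual_temperature,
                                               strict = FALSE))
    eps <- evaluate_permittivity(m, s$frequencies)
    r <- c(Re(eps) - s$eps_real, -Im(eps) - s$eps_imag)
    ss <- ss + sum(r^2)
    nn <- nn + length(r)
  }
  sqrt(ss / nn)
}

#' Tabulate several models on a common frequency grid
#'
#' Side-by-side forward evaluation for comparison and plotting: one row per
#' model and frequency with columns `label`, `frequency_Hz`, `eps_real`,
#' `eps_imag`.
#'
#' @param models Non-empty list of [cole_cole_model()] objects; names are
#'   used as labels when present, else each model's own label.
#' @param frequencies Positive frequency grid in Hz (length >= 1).
#' @return A long-format data.frame.
#' @export
compare_models <- function(models, frequencies) {
  stopifnot(is.list(models), length(models) >= 1L, length(frequencies) >= 1L)
  labels <- names(models)
  if (is.null(labels)) labels <- rep("", length(models))
  do.call(rbind, lapply(seq_along(models), function(i) {
    m <- models[[i]]
    lab <- if (nzchar(labels[i])) labels[i] else
      if (nzchar(m$label)) m$label else paste0("model_", i)
    out <- permittivity_parts(m, frequencies)
    cbind(data.frame(label = lab), out)
  }))
}

#' Pairwise permittivity differences against a baseline model
#'
#' @param models Named list of [cole_cole_model()] (length >= 2); the first
#'   (or `baseline`) entry is the reference.
#' @param frequencies Frequency grid in Hz.
#' @param baseline Index or name of the baseline model.
#' @return A data.frame with one row per non-baseline model: maximum and mean
#'   absolute differences of eps_real and eps_imag from the baseline.
#' @export
compare_summary <- function(models, frequencies, baseline = 1L) {
  stopifnot(length(models) >= 2L)
  tab <- compare_models(models, frequencies)
  labs <- unique(tab$label)
  base_lab <- if (is.character(baseline)) baseline else labs[baseline]
  base <- tab[tab$label == base_lab, ]
  others <- setdiff(labs, base_lab)
  do.call(rbind, lapply(others, function(lab) {
    cur <- tab[tab$label == lab, ]
    dr <- cur$eps_real - base$eps_real
    di <- cur$eps_imag - base$eps_imag
    data.frame(baseline = base_lab, model = lab,
               max_abs_d_eps_real = max(abs(dr)),
               mean_abs_d_eps_real = mean(abs(dr)),
               max_abs_d_eps_imag = max(abs(di)),
               mean_abs_d_eps_imag = mean(abs(di)))
  }))
}
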