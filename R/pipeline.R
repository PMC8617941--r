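#' @title Workflow orchestration: simulate, fit, evaluate, compare
#' @name pipeline
#' @description File-level entry points tying the stages into the study
#'   workflow (simulate a campaign, fit per-sweep models and temperature
#'   laws, evaluate and compare models, compute the uncertainty budget).
#'   Each writes plain-text outputs whose headers carry a hash of the run
#'   configuration, so every output is traceable to its inputs. A thin
#'   command-line wrapper over these functions ships in
#'   `inst/scripts/dieltemp-cli.R`.
NULL

# deterministic 31-adic rolling hash (mod 2^31 - 1), hex-formatted;
# a traceability fingerprint, not a cryptographic digest
config_hash <- function(config) {
  s <- jsonlite::toJSON(config, auto_unbox = TRUE, digits = NA, force = TRUE)
  bytes <- as.integer(charToRaw(as.character(s)))
  h <- 0
  for (b in bytes) h <- (h * 31 + b) %% 2147483647
  sprintf("%08x", h)
}

header_lines <- function(config, extra = character()) {
  c(sprintf("# config_hash: %s", config_hash(config)), extra)
}

write_csv_with_header <- function(tab, path, config, extra = character()) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(header_lines(config, extra), con)
  utils::write.csv(tab, con, row.names = FALSE)
  invisible(path)
}

#' Simulate a campaign and write it to disk
#'
#' @param out_dir Output campaign directory.
#' @param truth Generating [temperature_model()]; defaults to the packaged
#'   first-order muscle model.
#' @param design A [campaign_design()].
#' @param confounders A [confounder_config()].
#' @param with_validation If `TRUE`, also generates pre/post validation
#'   sweeps from `validation_reference` with the campaign noise scales.
#' @param validation_reference Reference [cole_cole_model()] for validation
#'   sweeps (defaults to a smooth one-pole stand-in for a saline reference).
#' @param overwrite Replace an existing directory?
#' @return The campaign directory path, invisibly.
#' @export
run_simulate <- function(out_dir, truth = muscle_temperature_model(),
                         design = campaign_design(),
                         confounders = confounder_config(),
                         with_validation = FALSE,
                         validation_reference = NULL,
                         overwrite = FALSE) {
  campaign <- generate_campaign(truth, design, confounders)
  if (with_validation) {
    ref <- validation_reference %||%
      cole_cole_model(5.45, 0.96, list(cole_pole(72.8, 8.4e-12, 0.013)),
                      "synthetic saline reference")
    campaign$validation <- generate_validation_sweeps(
      ref, n_pre = 3L, n_post = 3L,
      noise_sd = c(confounders$noise_sd_re, confounders$noise_sd_im),
      frequencies = design_frequencies(design),
      seed = design$seed + 1L)
  }
  write_campaign(campaign, out_dir, overwrite = overwrite)
  message("campaign written to ", out_dir,
          " (config hash ", config_hash(unclass(design)), ")")
  invisible(out_dir)
}

#' Fit a campaign: per-sweep models, then polynomial temperature laws
#'
#' Reads a campaign directory, fits every sweep, fits the five temperature
#' laws and writes: `model_orderN.json` (the fitted temperature model),
#' `sweep_parameters.csv` (per-sweep Cole-Cole parameters vs temperature)
#' and `diagnostics.json` (per-parameter R squared, campaign RMSE,
#' convergence counts). When the design has too few distinct set
#' temperatures for the requested order, the polynomial stage is skipped
#' with a message and only per-sweep results are written.
#'
#' @param campaign_dir Campaign directory as written by [write_campaign()].
#' @param order Polynomial order of the laws (1 or 2).
#' @param out_dir Output directory (created if missing).
#' @param aggregate Passed to [fit_parameter_polynomials()].
#' @return A list with `fits`, and when the polynomial stage ran, `tmodel`,
#'   `polynomials` and `rmse`; invisibly.
#' @export
run_fit <- function(campaign_dir, order = 1, out_dir, aggregate = "per_sweep") {
  campaign <- read_campaign(campaign_dir)
  if (length(campaign$sweeps) == 0L) stop("campaign has no sweeps", call. = FALSE)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  cfg <- list(campaign_dir = campaign_dir, order = order, aggregate = aggregate)
  fits <- lapply(campaign$sweeps, fit_single_pole)
  tab <- fit_params_table(fits)
  write_csv_with_header(tab, file.path(out_dir, "sweep_parameters.csv"), cfg)

  # the temperature design, not jitter within one setpoint, must support the
  # polynomial order: count distinct set temperatures when they are recorded
  set_t <- vapply(campaign$sweeps, `[[`, numeric(1), "set_temperature")
  design_t <- if (all(is.na(set_t))) tab$actual_temperature else set_t[!is.na(set_t)]
  result <- list(fits = fits)
  if (length(unique(design_t)) >= order + 2) {
    poly <- fit_parameter_polynomials(fits, order = order, aggregate = aggregate,
                                      label = sprintf("order-%d fit of %s",
                                                      order, campaign_dir))
    rmse <- suppressWarnings(model_rmse(poly$tmodel, campaign))
    write_temperature_model_json(
      poly$tmodel, file.path(out_dir, sprintf("model_order%d.json", order)))
    diag <- list(
      config_hash = config_hash(cfg),
      order = order,
      r_squared = lapply(poly$polynomials, `[[`, "r_squared"),
      campaign_rmse = rmse,
      n_sweeps = length(fits),
      n_converged = sum(vapply(fits, `[[`, logical(1), "converged"))
    )
    jsonlite::write_json(diag, file.path(out_dir, "diagnostics.json"),
                         auto_unbox = TRUE, digits = NA)
    result$tmodel <- poly$tmodel
    result$polynomials <- poly$polynomials
    result$rmse <- rmse
  } else {
    message("only ", length(unique(design_t)), " distinct set temperature(s); ",
            "skipping the polynomial stage (need ", order + 2, ")")
  }
  invisible(result)
}

#' Evaluate a temperature model on a temperature/frequency grid
#'
#' Tabulates eps_real and eps_imag for every requested temperature and
#' frequency and writes one CSV.
#'
#' @param model_json Path to a temperature-model JSON, or a
#'   [temperature_model()] object.
#' @param temperatures Temperatures in degrees Celsius (may be empty, which
#'   yields an empty table).
#' @param frequencies Frequencies in Hz.
#' @param out_csv Output CSV path.
#' @param force Evaluate temperatures outside the model validity range
#'   (extrapolation) instead of erroring.
#' @return The table, invisibly.
#' @export
run_evaluate <- function(model_json, temperatures, frequencies, out_csv,
                         force = FALSE) {
  tmodel <- if (inherits(model_json, "temperature_model")) model_json else
    read_temperature_model_json(model_json)
  cfg <- list(model = if (is.character(model_json)) model_json else tmodel$label,
              temperatures = temperatures, force = force)
  rows <- lapply(temperatures, function(T) {
    m <- if (force) {
      suppressWarnings(model_at_temperature(tmodel, T, strict = FALSE))
    } else {
      model_at_temperature(tmodel, T, strict = TRUE)
    }
    cbind(data.frame(temperature_C = T), permittivity_parts(m, frequencies))
  })
  tab <- if (length(rows)) do.call(rbind, rows) else
    data.frame(temperature_C = numeric(0), frequency_Hz = numeric(0),
               eps_real = numeric(0), eps_imag = numeric(0))
  write_csv_with_header(tab, out_csv, cfg)
  invisible(tab)
}

#' Compare Cole-Cole models against a baseline
#'
#' Writes the per-frequency comparison table and returns the pairwise
#' summary (max/mean absolute differences vs the first model).
#'
#' @param models Named list of [cole_cole_model()] objects or paths to model
#'   JSON files; at least 2. The first is the baseline.
#' @param frequencies Frequency grid in Hz.
#' @param out_csv Output CSV path for the long-format table.
#' @return The summary data.frame, invisibly.
#' @export
run_compare <- function(models, frequencies, out_csv) {
  stopifnot(length(models) >= 2L)
  models <- lapply(models, function(m) {
    if (inherits(m, "cole_cole_model")) m else read_model_json(m)
  })
  cfg <- list(labels = vapply(models, `[[`, character(1), "label"))
  tab <- compare_models(models, frequencies)
  write_csv_with_header(tab, out_csv, cfg)
  invisible(compare_summary(models, frequencies))
}

#' Uncertainty budget of a campaign's validation sweeps
#'
#' @param campaign_dir Campaign directory containing a `validation/`
#'   subdirectory.
#' @param out_csv Output CSV path.
#' @return The `uncertainty_estimate`, invisibly.
#' @export
run_uncertainty <- function(campaign_dir, out_csv) {
  campaign <- read_campaign(campaign_dir)
  if (is.null(campaign$validation)) {
    stop("campaign at ", campaign_dir, " has no validation sweeps", call. = FALSE)
  }
  est <- combined_uncertainty(campaign$validation)
  write_uncertainty_csv(est, out_csv)
  invisible(est)
}

#' Run the end-to-end recovery harness and write a JSON report
#'
#' @param out_json Output report path.
#' @inheritParams end_to_end_recovery
#' @return The `recovery_report`, invisibly.
#' @export
run_recover <- function(out_json, truth = muscle_temperature_model(),
                        design = campaign_design(),
                        confounders = confounder_config(), order = 1) {
  rep <- end_to_end_recovery(truth, design, confounders, order = order)
  cfg <- list(design = unclass(design), confounders = confounder_to_list(confounders),
              order = order)
  med <- vapply(LAW_NAMES, function(nm) {
    stats::median(rep$sweep_param_rel_error[[nm]])
  }, numeric(1))
  out <- list(
    config_hash = config_hash(cfg),
    order = order,
    campaign_rmse_refit = rep$rmse,
    campaign_rmse_truth = rep$rmse_truth,
    r_squared = as.list(rep$r_squared),
    coef_rel_error = rep$coef_rel_error,
    median_sweep_rel_bias = as.list(med)
  )
  jsonlite::write_json(out, out_json, auto_unbox = TRUE, digits = NA)
  invisible(rep)
}
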