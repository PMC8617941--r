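#' @title Measurement containers and campaign directory I/O
#' @name sweep-io
#' @description A `frequency_sweep` is one probe measurement: a frequency
#'   grid, real and imaginary relative permittivity, and metadata (actual and
#'   set temperature, contact pressure, sample weights). A
#'   `measurement_campaign` groups sweeps by set temperature with optional
#'   reference-liquid validation sweeps and an environment log. Campaigns
#'   round-trip to a plain-text directory: `manifest.yaml`, one CSV per sweep
#'   with `#`-prefixed metadata header lines, `environment.csv` and a
#'   `validation/` subdirectory.
NULL

#' Create a frequency sweep
#'
#' @param frequencies Strictly increasing frequency grid in Hz.
#' @param eps_real,eps_imag Real part and (non-negative) loss part of the
#'   relative permittivity at each frequency.
#' @param actual_temperature Sample temperature at the moment of measurement
#'   (degrees Celsius); this, not the set temperature, feeds model fits.
#' @param set_temperature Nominal water-bath set temperature (degrees Celsius).
#' @param sample_id,site_id Integer identifiers of the tissue sample and the
#'   probed location on it.
#' @param contact_pressure Probe-to-tissue contact pressure in kPa (optional).
#' @param weight_before,weight_after Sample weights in grams (optional),
#'   recorded to monitor dehydration.
#' @return An object of class `frequency_sweep`.
#' @export
frequency_sweep <- function(frequencies, eps_real, eps_imag,
                            actual_temperature = NA_real_,
                            set_temperature = NA_real_,
                            sample_id = NA_integer_, site_id = NA_integer_,
                            contact_pressure = NA_real_,
                            weight_before = NA_real_, weight_after = NA_real_) {
  frequencies <- as.numeric(frequencies)
  eps_real <- as.numeric(eps_real)
  eps_imag <- as.numeric(eps_imag)
  n <- length(frequencies)
  if (n < 1L) stop("empty frequency grid", call. = FALSE)
  if (length(eps_real) != n || length(eps_imag) != n) {
    stop("eps_real and eps_imag must match the frequency grid length", call. = FALSE)
  }
  if (anyNA(frequencies) || any(diff(frequencies) <= 0)) {
    stop("frequencies must be strictly increasing and free of NA", call. = FALSE)
  }
  structure(
    list(frequencies = frequencies, eps_real = eps_real, eps_imag = eps_imag,
         actual_temperature = as.numeric(actual_temperature),
         set_temperature = as.numeric(set_temperature),
         sample_id = as.integer(sample_id), site_id = as.integer(site_id),
         contact_pressure = as.numeric(contact_pressure),
         weight_before = as.numeric(weight_before),
         weight_after = as.numeric(weight_after)),
    class = "frequency_sweep"
  )
}

#' @export
print.frequency_sweep <- function(x, ...) {
  cat(sprintf(
    "Frequency sweep: %d points, %.3g-%.3g GHz, set T = %g degC, actual T = %g degC\n",
    length(x$frequencies), min(x$frequencies) / 1e9, max(x$frequencies) / 1e9,
    x$set_temperature, x$actual_temperature))
  invisible(x)
}

#' Pair of pre/post validation sweep sets on a reference liquid
#'
#' Validation sweeps bracket a measurement run: the probe measures a stable
#' reference liquid (e.g. 0.1 M saline) before and after the tissue sweeps,
#' against a known reference permittivity model. The uncertainty budget is
#' computed from this pair.
#'
#' @param pre_sweeps,post_sweeps Non-empty lists of [frequency_sweep()]
#'   objects sharing one frequency grid.
#' @param reference A [cole_cole_model()] for the reference liquid at its
#'   measurement temperature.
#' @return An object of class `validation_pair`.
#' @export
validation_pair <- function(pre_sweeps, post_sweeps, reference) {
  stopifnot(is.list(pre_sweeps), is.list(post_sweeps),
            inherits(reference, "cole_cole_model"))
  if (length(pre_sweeps) < 1L || length(post_sweeps) < 1L) {
    stop("need at least one pre and one post validation sweep", call. = FALSE)
  }
  all_sweeps <- c(pre_sweeps, post_sweeps)
  f0 <- all_sweeps[[1]]$frequencies
  same <- vapply(all_sweeps, function(s) {
    length(s$frequencies) == length(f0) && all(s$frequencies == f0)
  }, logical(1))
  if (!all(same)) stop("validation sweeps must share one frequency grid", call. = FALSE)
  structure(list(pre_sweeps = pre_sweeps, post_sweeps = post_sweeps,
                 reference = reference),
            class = "validation_pair")
}

#' Create a measurement campaign
#'
#' @param sweeps List of [frequency_sweep()] objects.
#' @param validation Optional [validation_pair()].
#' @param environment_log Optional data.frame of per-sweep environmental
#'   readings (room humidity, room temperature).
#' @param truth Optional [temperature_model()]; present exactly when the
#'   campaign is synthetic and records the generating model.
#' @param design,confounders Optional generator configurations, kept so a
#'   synthetic campaign is reproducible from its manifest.
#' @return An object of class `measurement_campaign`.
#' @export
measurement_campaign <- function(sweeps, validation = NULL,
                                 environment_log = NULL, truth = NULL,
                                 design = NULL, confounders = NULL) {
  stopifnot(is.list(sweeps))
  ok <- vapply(sweeps, inherits, logical(1), "frequency_sweep")
  if (!all(ok)) stop("sweeps must all be frequency_sweep objects", call. = FALSE)
  if (!is.null(validation)) stopifnot(inherits(validation, "validation_pair"))
  if (!is.null(truth)) stopifnot(inherits(truth, "temperature_model"))
  structure(
    list(sweeps = sweeps, validation = validation,
         environment_log = environment_log, truth = truth,
         design = design, confounders = confounders),
    class = "measurement_campaign"
  )
}

#' @export
print.measurement_campaign <- function(x, ...) {
  st <- vapply(x$sweeps, `[[`, numeric(1), "set_temperature")
  cat(sprintf("Measurement campaign: %d sweeps at %d set temperature(s)%s\n",
              length(x$sweeps), length(unique(st[!is.na(st)])),
              if (!is.null(x$truth)) " [synthetic]" else ""))
  if (!is.null(x$validation)) {
    cat(sprintf("  validation: %d pre + %d post reference sweeps\n",
                length(x$validation$pre_sweeps), length(x$validation$post_sweeps)))
  }
  invisible(x)
}

#' Is a campaign synthetic?
#'
#' A campaign is synthetic exactly when it carries the generating truth model.
#' @param campaign A [measurement_campaign()].
#' @return Logical scalar.
#' @export
is_synthetic <- function(campaign) {
  stopifnot(inherits(campaign, "measurement_campaign"))
  !is.null(campaign$truth)
}

fmt_num <- function(x) {
  # integers in Hz stay integral across round-trips; others keep full precision
  ifelse(is.finite(x) & x == round(x) & abs(x) < 2^53,
         sprintf("%.0f", x), sprintf("%.17g", x))
}

sweep_meta_fields <- c("actual_temperature", "set_temperature", "sample_id",
                       "site_id", "contact_pressure", "weight_before",
                       "weight_after")

write_sweep_csv <- function(sweep, path) {
  meta <- vapply(sweep_meta_fields, function(f) {
    v <- sweep[[f]]
    if (length(v) != 1L || is.na(v)) "NA" else fmt_num(v)
  }, character(1))
  hdr <- sprintf("# %s: %s", sweep_meta_fields, meta)
  body <- paste(fmt_num(sweep$frequencies),
                sprintf("%.17g", sweep$eps_real),
                sprintf("%.17g", sweep$eps_imag), sep = ",")
  writeLines(c(hdr, "frequency_Hz,eps_real,eps_imag", body), path)
  invisible(path)
}

read_sweep_csv <- function(path) {
  lines <- readLines(path)
  meta_lines <- grep("^#", lines, value = TRUE)
  meta <- list()
  for (ml in meta_lines) {
    kv <- sub("^#\\s*", "", ml)
    key <- sub(":.*$", "", kv)
    val <- trimws(sub("^[^:]*:", "", kv))
    meta[[key]] <- suppressWarnings(as.numeric(val))
  }
  tab <- utils::read.csv(path, comment.char = "#")
  need <- c("frequency_Hz", "eps_real", "eps_imag")
  if (!all(need %in% names(tab))) {
    stop("malformed sweep file ", path, ": need columns ",
         paste(need, collapse = ", "), call. = FALSE)
  }
  frequency_sweep(
    tab$frequency_Hz, tab$eps_real, tab$eps_imag,
    actual_temperature = meta$actual_temperature %||% NA_real_,
    set_temperature = meta$set_temperature %||% NA_real_,
    sample_id = meta$sample_id %||% NA_integer_,
    site_id = meta$site_id %||% NA_integer_,
    contact_pressure = meta$contact_pressure %||% NA_real_,
    weight_before = meta$weight_before %||% NA_real_,
    weight_after = meta$weight_after %||% NA_real_
  )
}

#' Write a campaign to a plain-text directory
#'
#' Layout: `manifest.yaml` (design, confounders, seed, truth-model file name),
#' `sweep_NNN.csv` per sweep (metadata as `#`-prefixed header lines),
#' `environment.csv`, and `validation/` with `pre_NN.csv`, `post_NN.csv` and
#' `reference_model.json`.
#'
#' @param campaign A [measurement_campaign()].
#' @param dir Output directory (created; must not already exist unless
#'   `overwrite = TRUE`).
#' @param overwrite Replace an existing directory?
#' @return `dir`, invisibly.
#' @export
write_campaign <- function(campaign, dir, overwrite = FALSE) {
  stopifnot(inherits(campaign, "measurement_campaign"))
  if (dir.exists(dir)) {
    if (!overwrite) stop("directory exists: ", dir, call. = FALSE)
    unlink(dir, recursive = TRUE)
  }
  # stage into a sibling temp dir, then atomic rename
  stage <- paste0(dir, ".staging-", Sys.getpid())
  dir.create(stage, recursive = TRUE)
  on.exit(unlink(stage, recursive = TRUE), add = TRUE)

  manifest <- list(
    format = "dieltemp-campaign-v1",
    n_sweeps = length(campaign$sweeps),
    synthetic = is_synthetic(campaign),
    design = campaign$design,
    confounders = campaign$confounders
  )
  yaml::write_yaml(manifest, file.path(stage, "manifest.yaml"))
  for (i in seq_along(campaign$sweeps)) {
    write_sweep_csv(campaign$sweeps[[i]],
                    file.path(stage, sprintf("sweep_%03d.csv", i)))
  }
  if (!is.null(campaign$environment_log)) {
    utils::write.csv(campaign$environment_log,
                     file.path(stage, "environment.csv"), row.names = FALSE)
  }
  if (!is.null(campaign$truth)) {
    write_temperature_model_json(campaign$truth,
                                 file.path(stage, "truth_model.json"))
  }
  if (!is.null(campaign$validation)) {
    vdir <- file.path(stage, "validation")
    dir.create(vdir)
    vp <- campaign$validation
    for (i in seq_along(vp$pre_sweeps)) {
      write_sweep_csv(vp$pre_sweeps[[i]], file.path(vdir, sprintf("pre_%02d.csv", i)))
    }
    for (i in seq_along(vp$post_sweeps)) {
      write_sweep_csv(vp$post_sweeps[[i]], file.path(vdir, sprintf("post_%02d.csv", i)))
    }
    write_model_json(vp$reference, file.path(vdir, "reference_model.json"))
  }
  if (!file.rename(stage, dir)) {
    stop("could not move staged campaign into place at ", dir, call. = FALSE)
  }
  on.exit()
  invisible(dir)
}

#' Read a campaign from a directory written by [write_campaign()]
#'
#' @param dir Campaign directory.
#' @return A [measurement_campaign()].
#' @export
read_campaign <- function(dir) {
  if (!dir.exists(dir)) stop("no such campaign directory: ", dir, call. = FALSE)
  mpath <- file.path(dir, "manifest.yaml")
  manifest <- if (file.exists(mpath)) yaml::read_yaml(mpath) else list()
  sweep_files <- sort(list.files(dir, pattern = "^sweep_\\d+\\.csv$",
                                 full.names = TRUE))
  sweeps <- lapply(sweep_files, read_sweep_csv)
  env <- NULL
  epath <- file.path(dir, "environment.csv")
  if (file.exists(epath)) env <- utils::read.csv(epath)
  truth <- NULL
  tpath <- file.path(dir, "truth_model.json")
  if (file.exists(tpath)) truth <- read_temperature_model_json(tpath)
  validation <- NULL
  vdir <- file.path(dir, "validation")
  if (dir.exists(vdir)) {
    pre <- lapply(sort(list.files(vdir, pattern = "^pre_\\d+\\.csv$",
                                  full.names = TRUE)), read_sweep_csv)
    post <- lapply(sort(list.files(vdir, pattern = "^post_\\d+\\.csv$",
                                   full.names = TRUE)), read_sweep_csv)
    ref <- read_model_json(file.path(vdir, "reference_model.json"))
    validation <- validation_pair(pre, post, ref)
  }
  measurement_campaign(sweeps, validation = validation, environment_log = env,
                       truth = truth, design = manifest$design,
                       confounders = manifest$confounders)
}
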