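#' @title Temperature-dependent single-pole Cole-Cole model
#' @name temperature-model
#' @description The five single-pole Cole-Cole parameters (eps_inf, sigma_s,
#'   delta_eps, tau, alpha) each follow a low-order polynomial in tissue
#'   temperature; a `temperature_model` bundles the five laws and instantiates
#'   an ordinary Cole-Cole model at any temperature in its validity range.
NULL

#' Names of the five single-pole Cole-Cole parameters
#' @keywords internal
LAW_NAMES <- c("eps_inf", "sigma_s", "delta_eps", "tau", "alpha")

law_bounds <- function(name) {
  # field invariants of the instantiated model; tau law is in picoseconds
  switch(name,
    eps_inf   = c(0, Inf),
    sigma_s   = c(0, Inf),
    delta_eps = c(.Machine$double.xmin, Inf),
    tau       = c(.Machine$double.xmin, Inf),
    alpha     = c(0, 1 - .Machine$double.eps)
  )
}

#' Create a polynomial temperature law for one Cole-Cole parameter
#'
#' A first-order law is `p0 + p1 * T`; a second-order law is
#' `q0 + q1 * T + q2 * T^2` (coefficients in ascending degree). Temperatures
#' are degrees Celsius. The `tau` law is expressed in picoseconds, matching
#' how such coefficients are conventionally tabulated; conversion to seconds
#' happens when a model is instantiated.
#'
#' On construction the law is evaluated on a dense grid over `temp_range` and
#' must yield values admissible for its parameter (e.g. `alpha` in `[0, 1)`).
#'
#' @param name One of `"eps_inf"`, `"sigma_s"`, `"delta_eps"`, `"tau"`,
#'   `"alpha"`.
#' @param coefficients Numeric vector of length `order + 1`, ascending degree.
#' @param temp_range Validity interval in degrees Celsius.
#' @param on_invalid `"error"` (default) rejects a law whose values leave the
#'   admissible range anywhere in `temp_range`; `"warn"` keeps it with a
#'   warning (used when laws are fitted to noisy data).
#' @return An object of class `temperature_law`.
#' @examples
#' temperature_law("sigma_s", c(0.9585, 0.0393)) # S/m, linear in T
#' @export
temperature_law <- function(name, coefficients,
                            temp_range = c(20, 45),
                            on_invalid = c("error", "warn")) {
  name <- match.arg(name, LAW_NAMES)
  on_invalid <- match.arg(on_invalid)
  coefficients <- as.numeric(coefficients)
  if (!length(coefficients) %in% c(2L, 3L) || anyNA(coefficients)) {
    stop("coefficients must be 2 (order 1) or 3 (order 2) finite numbers",
         call. = FALSE)
  }
  stopifnot(length(temp_range) == 2L, temp_range[1] < temp_range[2])
  law <- structure(
    list(name = name, order = length(coefficients) - 1L,
         coefficients = coefficients, temp_range = as.numeric(temp_range)),
    class = "temperature_law"
  )
  tt <- seq(temp_range[1], temp_range[2], length.out = 501L)
  v <- evaluate_law(law, tt)
  b <- law_bounds(name)
  if (any(v < b[1] | v >= ifelse(is.finite(b[2]), b[2] + .Machine$double.eps, Inf))) {
    msg <- sprintf(
      "law for %s leaves its admissible range within [%g, %g] degC (min %g, max %g)",
      name, temp_range[1], temp_range[2], min(v), max(v))
    if (on_invalid == "error") stop(msg, call. = FALSE) else warning(msg, call. = FALSE)
  }
  law
}

#' Evaluate a temperature law at given temperatures
#'
#' @param law A [temperature_law()].
#' @param temperature Numeric vector, degrees Celsius.
#' @return Numeric vector of parameter values (picoseconds for the `tau` law).
#' @export
evaluate_law <- function(law, temperature) {
  stopifnot(inherits(law, "temperature_law"))
  drop(outer(as.numeric(temperature), seq_along(law$coefficients) - 1, `^`) %*%
         law$coefficients)
}

#' Bundle five temperature laws into a temperature-dependent model
#'
#' @param laws List of five [temperature_law()] objects, one per parameter
#'   name, all sharing the same `temp_range`.
#' @param label Free-text provenance label.
#' @return An object of class `temperature_model`.
#' @export
temperature_model <- function(laws, label = "") {
  stopifnot(is.list(laws))
  names(laws) <- vapply(laws, function(l) l$name, character(1))
  if (!setequal(names(laws), LAW_NAMES) || length(laws) != 5L) {
    stop("need exactly five laws, one per parameter: ",
         paste(LAW_NAMES, collapse = ", "), call. = FALSE)
  }
  laws <- laws[LAW_NAMES]
  rng <- vapply(laws, function(l) l$temp_range, numeric(2))
  if (any(rng[1, ] != rng[1, 1]) || any(rng[2, ] != rng[2, 1])) {
    stop("all laws must share one temp_range", call. = FALSE)
  }
  structure(list(laws = laws, temp_range = laws[[1]]$temp_range,
                 label = as.character(label)),
            class = "temperature_model")
}

#' @export
print.temperature_model <- function(x, ...) {
  cat(sprintf("Temperature-dependent single-pole Cole-Cole model%s, valid %g-%g degC\n",
              if (nzchar(x$label)) paste0(" [", x$label, "]") else "",
              x$temp_range[1], x$temp_range[2]))
  for (l in x$laws) {
    cat(sprintf("  %-9s order %d: %s%s\n", l$name, l$order,
                paste(signif(l$coefficients, 6), collapse = ", "),
                if (l$name == "tau") "  (picoseconds)" else ""))
  }
  invisible(x)
}

#' Instantiate a Cole-Cole model at a given temperature
#'
#' Evaluates each of the five laws at `temperature` and assembles a
#' single-pole [cole_cole_model()]; the `tau` law value is converted from
#' picoseconds to seconds.
#'
#' @param tmodel A [temperature_model()].
#' @param temperature Temperature in degrees Celsius.
#' @param strict If `TRUE` (default), a temperature outside the model's
#'   validity range is an error; if `FALSE` it only warns (extrapolation).
#' @return A single-pole [cole_cole_model()].
#' @details A law fitted to noisy or misspecified data can stray marginally
#'   outside its parameter's admissible range near the edges of the
#'   temperature interval (e.g. a small negative `eps_inf`); evaluated values
#'   are clamped to the admissible range with a warning so the model remains
#'   physical.
#' @examples
#' tm <- muscle_temperature_model()
#' model_at_temperature(tm, 37)$sigma_s # 2.4126 S/m
#' @export
model_at_temperature <- function(tmodel, temperature, strict = TRUE) {
  stopifnot(inherits(tmodel, "temperature_model"), length(temperature) == 1L)
  r <- tmodel$temp_range
  if (temperature < r[1] || temperature > r[2]) {
    msg <- sprintf("temperature %g degC outside validity range [%g, %g]",
                   temperature, r[1], r[2])
    if (strict) stop(msg, call. = FALSE) else warning(msg, call. = FALSE)
  }
  v <- vapply(tmodel$laws, evaluate_law, numeric(1), temperature = temperature)
  for (nm in names(v)) {
    b <- law_bounds(nm)
    if (v[[nm]] < b[1] || v[[nm]] > b[2]) {
      warning(sprintf("%s law value %g at %g degC clamped into [%g, %g]",
                      nm, v[[nm]], temperature, b[1], min(b[2], 1)),
              call. = FALSE)
      v[[nm]] <- min(max(v[[nm]], b[1]), b[2])
    }
  }
  cole_cole_model(
    eps_inf = v[["eps_inf"]], sigma_s = v[["sigma_s"]],
    poles = list(cole_pole(v[["delta_eps"]], v[["tau"]] * 1e-12, v[["alpha"]])),
    label = sprintf("%s at %g degC", tmodel$label, temperature)
  )
}

#' Temperature crossover frequency of the real permittivity
#'
#' For high-water-content tissue the real permittivity decreases with
#' temperature at low microwave frequencies and increases with temperature
#' above a crossover. This finds the frequency where the
#' \eqn{\epsilon'} curves at two temperatures intersect, by bisection on
#' \eqn{g(f) = \epsilon'(f, T_1) - \epsilon'(f, T_2)} to relative tolerance
#' 1e-9.
#'
#' @param tmodel A [temperature_model()].
#' @param t1,t2 Two distinct temperatures in degrees Celsius.
#' @param f_lo,f_hi Search bracket in Hz, `f_lo < f_hi`.
#' @param n_scan Number of log-spaced scan points used to locate sign changes.
#' @return Crossover frequency in Hz, or `NA_real_` when the two curves do
#'   not cross on the bracket.
#' @examples
#' tm <- muscle_temperature_model()
#' crossover_frequency(tm, 20, 45, 0.5e9, 40e9) / 1e9 # ~6.5 GHz
#' @export
crossover_frequency <- function(tmodel, t1, t2, f_lo, f_hi, n_scan = 4096L) {
  stopifnot(inherits(tmodel, "temperature_model"))
  if (t1 == t2) stop("t1 and t2 must differ", call. = FALSE)
  if (!(f_lo > 0 && f_lo < f_hi)) stop("need 0 < f_lo < f_hi", call. = FALSE)
  m1 <- model_at_temperature(tmodel, t1)
  m2 <- model_at_temperature(tmodel, t2)
  g <- function(f) Re(evaluate_permittivity(m1, f)) - Re(evaluate_permittivity(m2, f))
  fs <- exp(seq(log(f_lo), log(f_hi), length.out = n_scan))
  gv <- g(fs)
  s <- sign(gv)
  # treat exact zeros as roots; detect strict sign changes between scan points
  flips <- which(s[-1] * s[-length(s)] < 0)
  zeros <- which(s == 0)
  if (length(zeros) > 0 && all(s == 0)) return(NA_real_) # identical curves
  if (length(flips) == 0L && length(zeros) == 0L) return(NA_real_)
  if (length(flips) + length(zeros) > 1L && length(zeros) == 0L) {
    brk <- paste(sprintf("[%.6g, %.6g] Hz", fs[flips], fs[flips + 1]),
                 collapse = ", ")
    stop("multiple sign changes on bracket; sub-brackets: ", brk, call. = FALSE)
  }
  if (length(zeros) == 1L && length(flips) == 0L) return(fs[zeros])
  lo <- fs[flips[1]]; hi <- fs[flips[1] + 1]
  glo <- g(lo)
  while ((hi - lo) / hi > 1e-9) {
    mid <- (lo + hi) / 2
    gm <- g(mid)
    if (gm == 0) return(mid)
    if (sign(gm) == sign(glo)) { lo <- mid; glo <- gm } else hi <- mid
  }
  (lo + hi) / 2
}

#' Write a temperature model to JSON
#'
#' Serializes as `{label, temp_range_C, laws:{name:{order, coefficients}}}`
#' with coefficients in ascending degree and the `tau` law in picoseconds.
#'
#' @param tmodel A [temperature_model()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_temperature_model_json <- function(tmodel, path) {
  stopifnot(inherits(tmodel, "temperature_model"))
  obj <- list(
    label = tmodel$label,
    temp_range_C = tmodel$temp_range,
    laws = lapply(tmodel$laws, function(l) {
      list(order = l$order, coefficients = l$coefficients)
    })
  )
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a temperature model from JSON
#'
#' @param path Path to a JSON file written by [write_temperature_model_json()].
#' @param on_invalid Passed to [temperature_law()].
#' @return A [temperature_model()].
#' @export
read_temperature_model_json <- function(path, on_invalid = "error") {
  obj <- jsonlite::read_json(path)
  rng <- unlist(obj$temp_range_C)
  laws <- lapply(names(obj$laws), function(nm) {
    temperature_law(nm, unlist(obj$laws[[nm]]$coefficients),
                    temp_range = rng, on_invalid = on_invalid)
  })
  temperature_model(laws, label = obj$label %||% "")
}
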