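#' @title Multi-pole Cole-Cole permittivity models
#' @name cole-cole
#' @description Constructors and forward evaluation for Cole-Cole relaxation
#'   models of complex relative permittivity, the workhorse description of
#'   tissue dielectric dispersion in the microwave band.
NULL

#' Vacuum permittivity (F/m), CODATA value
#'
#' Fixed so that printed-precision checks of conductivity terms are
#' reproducible across platforms.
#' @export
EPS0 <- 8.8541878128e-12

#' Create a single Cole-Cole relaxation pole
#'
#' A pole is one relaxation process contributing a step of height
#' `delta_eps` in the real permittivity and a loss peak around its relaxation
#' frequency \eqn{(2\pi\tau)^{-1}}. The broadening exponent `alpha`
#' symmetrically widens the dispersion; `alpha = 0` recovers a Debye pole.
#'
#' @param delta_eps Permittivity increment (dimensionless, > 0).
#' @param tau Relaxation time in seconds (> 0).
#' @param alpha Broadening exponent in `[0, 1)`.
#' @return An object of class `cole_pole`.
#' @examples
#' gamma_pole <- cole_pole(delta_eps = 50, tau = 7.23e-12, alpha = 0.1)
#' relaxation_frequency(gamma_pole) / 1e9 # ~22 GHz
#' @export
cole_pole <- function(delta_eps, tau, alpha) {
  stopifnot(length(delta_eps) == 1L, length(tau) == 1L, length(alpha) == 1L)
  if (!is.finite(delta_eps) || !is.finite(tau) || !is.finite(alpha)) {
    stop("cole_pole parameters must be finite numbers", call. = FALSE)
  }
  if (delta_eps <= 0) stop("delta_eps must be > 0", call. = FALSE)
  if (tau <= 0) stop("tau must be > 0 (seconds)", call. = FALSE)
  if (alpha < 0 || alpha >= 1) stop("alpha must satisfy 0 <= alpha < 1", call. = FALSE)
  structure(
    list(delta_eps = as.numeric(delta_eps), tau = as.numeric(tau),
         alpha = as.numeric(alpha)),
    class = "cole_pole"
  )
}

#' Create a Cole-Cole model
#'
#' A model is a high-frequency permittivity limit `eps_inf`, a static ionic
#' conductivity `sigma_s` and an ordered list of relaxation poles. With the
#' sign convention \eqn{\epsilon = \epsilon' - j\epsilon''} the model is
#' \deqn{\epsilon(f) = \epsilon_\infty + \sum_n
#'   \frac{\Delta\epsilon_n}{1 + (j 2\pi f \tau_n)^{1-\alpha_n}}
#'   + \frac{\sigma_s}{j 2\pi f \epsilon_0}.}
#'
#' `eps_inf` is bounded below by 0, not 1: fitted temperature laws for
#' high-water tissue can legitimately take `eps_inf` below 1 near the top of
#' their temperature range.
#'
#' @param eps_inf High-frequency relative permittivity (>= 0).
#' @param sigma_s Static conductivity in S/m (>= 0).
#' @param poles List of [cole_pole()] objects (may be empty).
#' @param label Free-text provenance label.
#' @return An object of class `cole_cole_model`.
#' @examples
#' m <- cole_cole_model(4, 0.2, list(cole_pole(50, 7.23e-12, 0.1)), "gamma only")
#' evaluate_permittivity(m, 2.45e9)
#' @export
cole_cole_model <- function(eps_inf, sigma_s, poles = list(), label = "") {
  stopifnot(length(eps_inf) == 1L, length(sigma_s) == 1L, is.list(poles))
  if (!is.finite(eps_inf) || !is.finite(sigma_s)) {
    stop("eps_inf and sigma_s must be finite numbers", call. = FALSE)
  }
  if (eps_inf < 0) stop("eps_inf must be >= 0", call. = FALSE)
  if (sigma_s < 0) stop("sigma_s must be >= 0 (S/m)", call. = FALSE)
  poles <- lapply(poles, function(p) {
    if (inherits(p, "cole_pole")) p else do.call(cole_pole, p)
  })
  structure(
    list(eps_inf = as.numeric(eps_inf), sigma_s = as.numeric(sigma_s),
         poles = poles, label = as.character(label)),
    class = "cole_cole_model"
  )
}

#' @export
print.cole_pole <- function(x, ...) {
  cat(sprintf("Cole-Cole pole: delta_eps = %g, tau = %g s (f_rel = %g Hz), alpha = %g\n",
              x$delta_eps, x$tau, relaxation_frequency(x), x$alpha))
  invisible(x)
}

#' @export
print.cole_cole_model <- function(x, ...) {
  cat(sprintf("Cole-Cole model%s: eps_inf = %g, sigma_s = %g S/m, %d pole(s)\n",
              if (nzchar(x$label)) paste0(" [", x$label, "]") else "",
              x$eps_inf, x$sigma_s, length(x$poles)))
  for (p in x$poles) {
    cat(sprintf("  delta_eps = %g, tau = %g s, alpha = %g\n",
                p$delta_eps, p$tau, p$alpha))
  }
  invisible(x)
}

#' Evaluate complex relative permittivity on a frequency grid
#'
#' Vectorized forward evaluation of a Cole-Cole model. The returned complex
#' values follow the engineering convention
#' \eqn{\epsilon = \epsilon' - j\epsilon''}; the conductivity term
#' \eqn{\sigma_s/(j 2\pi f \epsilon_0)} therefore contributes
#' \eqn{+\sigma_s/(2\pi f \epsilon_0)} to the loss \eqn{\epsilon''}.
#'
#' @param model A [cole_cole_model()].
#' @param frequencies Numeric vector of frequencies in Hz, all > 0.
#' @return Complex vector of the same length as `frequencies`.
#' @examples
#' m <- cole_cole_model(4, 0, list())
#' evaluate_permittivity(m, c(1e9, 1e10)) # 4 + 0i at all f
#' @export
evaluate_permittivity <- function(model, frequencies) {
  stopifnot(inherits(model, "cole_cole_model"))
  frequencies <- as.numeric(frequencies)
  if (length(frequencies) == 0L) return(complex(0))
  if (anyNA(frequencies)) stop("frequencies must not contain NA", call. = FALSE)
  if (any(frequencies <= 0)) stop("all frequencies must be > 0 Hz", call. = FALSE)
  w <- 2 * pi * frequencies
  eps <- complex(real = rep(model$eps_inf, length(w)), imaginary = 0)
  for (p in model$poles) {
    eps <- eps + p$delta_eps / (1 + (1i * w * p$tau)^(1 - p$alpha))
  }
  if (model$sigma_s > 0) {
    eps <- eps + model$sigma_s / (1i * w * EPS0)
  }
  eps
}

#' Real and imaginary permittivity parts as non-negative columns
#'
#' Convenience wrapper around [evaluate_permittivity()] returning a data frame
#' with `frequency_Hz`, `eps_real` (\eqn{\epsilon'}) and `eps_imag`
#' (\eqn{\epsilon''}, the non-negative loss magnitude).
#'
#' @inheritParams evaluate_permittivity
#' @return A data.frame with columns `frequency_Hz`, `eps_real`, `eps_imag`.
#' @export
permittivity_parts <- function(model, frequencies) {
  eps <- evaluate_permittivity(model, frequencies)
  data.frame(frequency_Hz = as.numeric(frequencies),
             eps_real = Re(eps), eps_imag = -Im(eps))
}

#' Relaxation frequency of a pole
#'
#' Returns \eqn{(2\pi\tau)^{-1}} in Hz, the frequency of the loss peak of a
#' Debye pole and the centre of the broadened Cole-Cole dispersion.
#'
#' @param pole A [cole_pole()] or a positive relaxation time in seconds.
#' @return Frequency in Hz.
#' @examples
#' relaxation_frequency(353.68e-9) / 1e6 # 0.45 MHz: a delta-dispersion pole
#' @export
relaxation_frequency <- function(pole) {
  tau <- if (inherits(pole, "cole_pole")) pole$tau else as.numeric(pole)
  stopifnot(length(tau) == 1L)
  if (!is.finite(tau) || tau <= 0) stop("tau must be > 0 (seconds)", call. = FALSE)
  1 / (2 * pi * tau)
}

#' Write a Cole-Cole model to JSON
#'
#' Serializes as `{label, eps_inf, sigma_s, poles:[{delta_eps, tau_s, alpha}]}`
#' with relaxation times in seconds.
#'
#' @param model A [cole_cole_model()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_model_json <- function(model, path) {
  stopifnot(inherits(model, "cole_cole_model"))
  obj <- list(
    label = model$label,
    eps_inf = model$eps_inf,
    sigma_s = model$sigma_s,
    poles = lapply(model$poles, function(p) {
      list(delta_eps = p$delta_eps, tau_s = p$tau, alpha = p$alpha)
    })
  )
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a Cole-Cole model from JSON
#'
#' @param path Path to a JSON file written by [write_model_json()].
#' @return A [cole_cole_model()].
#' @export
read_model_json <- function(path) {
  obj <- jsonlite::read_json(path)
  poles <- lapply(obj$poles, function(p) {
    cole_pole(delta_eps = p$delta_eps, tau = p$tau_s, alpha = p$alpha)
  })
  cole_cole_model(eps_inf = obj$eps_inf, sigma_s = obj$sigma_s,
                  poles = poles, label = obj$label %||% "")
}

`%||%` <- function(a, b) if (is.null(a)) b else a
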