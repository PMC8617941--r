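# Independent oracles, deliberately sharing no code with the package.

# Hand-coded scalar Cole-Cole evaluation via explicit polar arithmetic.
# poles: list of numeric triples c(delta_eps, tau_s, alpha).
scalar_cole_cole <- function(f, eps_inf, sigma_s, poles) {
  e0 <- 8.8541878128e-12
  re <- eps_inf
  im <- 0
  for (p in poles) {
    x <- (2 * pi * f * p[2])^(1 - p[3])
    ang <- (pi / 2) * (1 - p[3])
    dr <- 1 + x * cos(ang)
    di <- x * sin(ang)
    den <- dr * dr + di * di
    re <- re + p[1] * dr / den
    im <- im - p[1] * di / den
  }
  im <- im - sigma_s / (2 * pi * f * e0)
  complex(real = re, imaginary = im)
}

# Separately implemented Debye + conductivity formula.
debye_eval <- function(f, eps_inf, delta_eps, tau, sigma_s = 0) {
  e0 <- 8.8541878128e-12
  eps_inf + delta_eps / (1 + 1i * 2 * pi * f * tau) +
    sigma_s / (1i * 2 * pi * f * e0)
}

# Noise-free sweep sampled from a model on a grid.
sweep_from_model <- function(model, frequencies, actual_temperature = NA_real_,
                             set_temperature = NA_real_) {
  eps <- evaluate_permittivity(model, frequencies)
  frequency_sweep(frequencies, Re(eps), -Im(eps),
                  actual_temperature = actual_temperature,
                  set_temperature = set_temperature)
}

# Minimal fit_result stand-in for feeding the polynomial stage directly.
fake_fit <- function(eps_inf, sigma_s, delta_eps, tau_ps, alpha, temperature) {
  structure(
    list(model = cole_cole_model(eps_inf, sigma_s,
                                 list(cole_pole(delta_eps, tau_ps * 1e-12, alpha))),
         residual_norm = 0, n_iterations = 0L, converged = TRUE,
         covariance_proxy = NULL, actual_temperature = temperature),
    class = "fit_result"
  )
}

# The study-design frequency grid (0.5-40 GHz in 25 MHz steps).
study_grid <- function() seq(0.5e9, 40e9, by = 25e6)

rel_err <- function(a, b) abs(a - b) / pmax(abs(b), .Machine$double.xmin)
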