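#' Registry of published muscle Cole-Cole models at 37 degC
#'
#' Returns the five muscle-tissue models tabulated in the literature-comparison
#' table: the two-pole Gabriel model (gamma + delta dispersion), the one-pole
#' Peyman and Abdilla models, the two-pole Ley model, and the one-pole model
#' of this package's reference temperature study evaluated at 37 degC.
#' Parameters match the printed table values; relaxation times are stored in
#' seconds (the tables print the gamma pole tau in picoseconds and the delta
#' pole tau in nanoseconds).
#'
#' @return Named list of [cole_cole_model()] objects, one per literature label.
#' @examples
#' names(literature_models())
#' relaxation_frequency(literature_models()$Gabriel$poles[[2]]) / 1e6 # 0.45 MHz
#' @export
literature_models <- function() {
  path <- system.file("extdata", "literature_models_37C.json",
                      package = "dieltemp", mustWork = TRUE)
  obj <- jsonlite::read_json(path)
  models <- lapply(obj$models, function(m) {
    cole_cole_model(
      eps_inf = m$eps_inf, sigma_s = m$sigma_s,
      poles = lapply(m$poles, function(p) {
        cole_pole(p$delta_eps, p$tau_s, p$alpha)
      }),
      label = m$label
    )
  })
  names(models) <- vapply(obj$models, `[[`, character(1), "label")
  models
}

#' The published temperature-dependent muscle model
#'
#' The packaged polynomial temperature laws for the five single-pole
#' Cole-Cole parameters of porcine muscle, valid for 20-45 degC and
#' 0.5-40 GHz. `order = 1` returns the adopted linear laws; `order = 2`
#' returns the quadratic alternative whose marginal goodness-of-fit
#' improvement did not justify the added complexity.
#'
#' @param order Polynomial order of the laws, 1 (default) or 2.
#' @return A [temperature_model()].
#' @examples
#' tm <- muscle_temperature_model()
#' model_at_temperature(tm, 37)
#' @export
muscle_temperature_model <- function(order = 1) {
  stopifnot(order %in% c(1, 2))
  fname <- sprintf("muscle_temperature_model_order%d.json", order)
  path <- system.file("extdata", fname, package = "dieltemp", mustWork = TRUE)
  read_temperature_model_json(path)
}
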