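# dieltemp

Temperature-dependent Cole–Cole dielectric modelling of muscle tissue over
0.5–40 GHz and 20–45 °C.

Electromagnetic applicators for diagnosis and therapy — microwave imaging,
ablation, hyperthermia — are designed against dielectric tissue models, and
tissue permittivity shifts by roughly 2% per °C. `dieltemp` provides the
modelling side of an ultra-wideband, temperature-resolved dielectric study
of high-water-content tissue: forward evaluation of multi-pole Cole–Cole
models, a temperature-dependent single-pole model whose five parameters
follow polynomial laws in tissue temperature, bounded Levenberg–Marquardt
fitting of complex permittivity sweeps, a measurement-uncertainty budget
from reference-liquid validation sweeps, and a synthetic campaign generator
that emulates a controlled open-ended coaxial probe study design.

## The model

Complex relative permittivity with the convention ε = ε′ − jε″:

    ε(f, T) = ε∞(T) + Δε(T) / (1 + (j2πf τ(T))^(1−α(T))) + σs(T) / (j2πf ε0)

Each parameter follows a polynomial law in temperature T (°C), linear by
default (`p0 + p1·T`), valid over 20–45 °C. The packaged muscle laws are

| parameter | p1 | p0 |
|---|---|---|
| ε∞ | −0.0746 | 3.7529 |
| σs [S/m] | 0.0393 | 0.9585 |
| Δε | −0.1545 | 59.7534 |
| τ [ps] | −0.1243 | 11.7765 |
| α | −0.0014 | 0.1646 |

together with second-order alternatives and a registry of five published
muscle models at 37 °C (`literature_models()`).

## Worked example

```r
library(dieltemp)

tm <- muscle_temperature_model()          # packaged first-order laws
m37 <- model_at_temperature(tm, 37)       # single-pole model at 37 degC
m37
#> Cole-Cole model [muscle first-order temperature model at 37 degC]:
#>   eps_inf = 0.9927, sigma_s = 2.4126 S/m, 1 pole(s)
#>   delta_eps = 54.0369, tau = 7.1774e-12 s, alpha = 0.1128

permittivity_parts(m37, c(2.45e9, 5.8e9, 24.125e9))   # ISM bands
#>   frequency_Hz eps_real eps_imag
#> 1   2.4500e+09 52.75533 24.74245
#> 2   5.8000e+09 48.44446 20.96611
#> 3   2.4125e+10 26.29554 24.35408

crossover_frequency(tm, 20, 45, 0.5e9, 40e9) / 1e9
#> [1] 6.534089
```

At 2.45 GHz body-temperature muscle has ε′ ≈ 52.8 and a loss ε″ ≈ 24.7
dominated by ionic conductivity; the real-permittivity curves at 20 °C and
45 °C cross at 6.53 GHz — below it, warming lowers ε′, above it the
opposite.

The synthetic pipeline round-trips the model through a full emulated
campaign (72 sweeps of 1581 points, temperature jitter, pressure effect,
additive noise of scale 0.5 on both parts):

```r
rep <- end_to_end_recovery(tm, campaign_design(seed = 1), confounder_config())
rep
#> End-to-end recovery (order-1 laws, 72 sweeps)
#>   campaign RMSE: refit 0.5024, truth 0.5037
#>   median per-sweep relative bias:
#>     eps_inf   -0.223%
#>     sigma_s   +0.118%
#>     delta_eps +0.129%
#>     tau       +0.0162%
#>     alpha     +0.273%
```

The refit RMSE equals the injected noise scale and the per-parameter biases
are a fraction of a percent.

A thin command-line wrapper over the same functions ships in
`inst/scripts/dieltemp-cli.R` (`simulate`, `fit`, `evaluate`, `compare`,
`uncertainty`, `recover`).

## Package layout

- `R/` — model types and evaluation, temperature laws, fitting,
  uncertainty budget, synthetic campaigns, pipeline entry points
- `inst/extdata/` — packaged model parameters (JSON)
- `vignettes/temperature-dependent-dielectric-modelling.Rmd` — the methods
  account: model assumptions, fitting choices, what the generator does and
  does not emulate
- `tests/testthat/` — unit, property and end-to-end suites
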