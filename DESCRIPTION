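Package: dieltemp
Title: Temperature-Dependent Cole-Cole Dielectric Modelling of Muscle Tissue
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for ultra-wideband (0.5-40 GHz) dielectric modelling of
    high-water-content tissue over the 20-45 degree Celsius range. Provides
    forward evaluation of multi-pole Cole-Cole permittivity models, a
    temperature-dependent single-pole model whose five parameters follow
    polynomial laws in tissue temperature, bounded Levenberg-Marquardt fitting
    of complex permittivity sweeps, polynomial temperature-law regression with
    goodness-of-fit diagnostics, a combined measurement-uncertainty budget
    (random, systematic, drift) from reference-liquid validation sweeps, and a
    synthetic measurement-campaign generator that emulates an open-ended
    coaxial probe study design including temperature jitter, additive complex
    noise, contact-pressure sensitivity, dehydration monitoring and an
    unmodelled delta-dispersion tail.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    minpack.lm,
    jsonlite,
    yaml,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
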