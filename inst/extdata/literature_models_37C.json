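{
  "comment": "Cole-Cole parameters for muscle tissue at 37 degC as printed in the source tables; tau in seconds.",
  "models": [
    {
      "label": "Gabriel",
      "eps_inf": 4.00,
      "sigma_s": 0.20,
      "poles": [
        {"delta_eps": 50.00, "tau_s": 7.23e-12, "alpha": 0.10},
        {"delta_eps": 7000, "tau_s": 353.68e-9, "alpha": 0.10}
      ]
    },
    {
      "label": "Peyman",
      "eps_inf": 3.00,
      "sigma_s": 0.11,
      "poles": [
        {"delta_eps": 46.64, "tau_s": 12.21e-12, "alpha": 0.10}
      ]
    },
    {
      "label": "Abdilla",
      "eps_inf": 11.78,
      "sigma_s": 0.95,
      "poles": [
        {"delta_eps": 39.45, "tau_s": 9.17e-12, "alpha": 0.10}
      ]
    },
    {
      "label": "Ley",
      "eps_inf": 4.75,
      "sigma_s": 0.53,
      "poles": [
        {"delta_eps": 50.73, "tau_s": 6.62e-12, "alpha": 0.18},
        {"delta_eps": 7000, "tau_s": 311.03e-9, "alpha": 0.18}
      ]
    },
    {
      "label": "This work (37 °C)",
      "eps_inf": 1.23,
      "sigma_s": 2.41,
      "poles": [
        {"delta_eps": 53.73, "tau_s": 7.21e-12, "alpha": 0.11}
      ]
    }
  ]
}
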