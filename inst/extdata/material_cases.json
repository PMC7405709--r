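{
  "description": "One-term Ogden stiffness cases for cornea and sclera spanning the physiological range. Units: mu in MPa, alpha dimensionless, d1 in 1/MPa (0 = incompressible). nominal_E_* are descriptive operating-point Young-modulus labels (MPa at 15 mm Hg) attached to each case; they are metadata, not derived quantities. Cases 6-8 reuse the case-5 scleral parameters (sclera held constant while the cornea stiffens).",
  "cases": [
    {"label": 1, "cornea": {"mu": [0.0084], "alpha": [13.312], "d1": 0}, "sclera": {"mu": [0.0254], "alpha": [23.716], "d1": 0}, "nominal_E_cornea": 0.108, "nominal_E_sclera": 0.325},
    {"label": 2, "cornea": {"mu": [0.0109], "alpha": [32.192], "d1": 0}, "sclera": {"mu": [0.0289], "alpha": [63.49],  "d1": 0}, "nominal_E_cornea": 0.325, "nominal_E_sclera": 0.974},
    {"label": 3, "cornea": {"mu": [0.0120], "alpha": [88.684], "d1": 0}, "sclera": {"mu": [0.0302], "alpha": [182.73], "d1": 0}, "nominal_E_cornea": 0.974, "nominal_E_sclera": 2.923},
    {"label": 4, "cornea": {"mu": [0.0124], "alpha": [258.09], "d1": 0}, "sclera": {"mu": [0.0307], "alpha": [540.4],  "d1": 0}, "nominal_E_cornea": 2.923, "nominal_E_sclera": 8.770},
    {"label": 5, "cornea": {"mu": [0.0114], "alpha": [46.321], "d1": 0}, "sclera": {"mu": [0.0302], "alpha": [182.73], "d1": 0}, "nominal_E_cornea": 0.487, "nominal_E_sclera": 2.923},
    {"label": 6, "cornea": {"mu": [0.0120], "alpha": [88.684], "d1": 0}, "sclera": {"mu": [0.0302], "alpha": [182.73], "d1": 0}, "nominal_E_cornea": 0.974, "nominal_E_sclera": 2.923},
    {"label": 7, "cornea": {"mu": [0.0123], "alpha": [173.39], "d1": 0}, "sclera": {"mu": [0.0302], "alpha": [182.73], "d1": 0}, "nominal_E_cornea": 1.949, "nominal_E_sclera": 2.923},
    {"label": 8, "cornea": {"mu": [0.0125], "alpha": [342.8],  "d1": 0}, "sclera": {"mu": [0.0302], "alpha": [182.73], "d1": 0}, "nominal_E_cornea": 3.898, "nominal_E_sclera": 2.923}
  ]
}
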