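{
  "stock": "WEST",
  "description": "Published biometric relationships for the Western Atlantic bluefin tuna stock, stored verbatim. Linear rows: y = alpha + beta * x. Power rows: y = alpha * x^beta. Method A: robust linear fit; B: CV-weighted nonlinear fit; C: Gauss-Newton nonlinear fit. Lengths cm, weights kg. Ranges are stored exactly as printed.",
  "linear": [
    {"x_type": "CFL", "y_type": "SFL", "x_min": 55, "x_max": 274, "y_min": 53, "y_max": 265, "n": 1035, "months": "3, 6-10", "alpha": 1.8575,  "beta": 0.9606, "r2": 0.991, "residual_se": 2.565,  "method": "A"},
    {"x_type": "SFL", "y_type": "CFL", "x_min": 53, "x_max": 265, "y_min": 55, "y_max": 274, "n": 1035, "months": "3, 6-10", "alpha": -0.8319, "beta": 1.0314, "r2": 0.991, "residual_se": 2.670,  "method": "A"},
    {"x_type": "DWT", "y_type": "RWT", "x_min": 93, "x_max": 637, "y_min": 70, "y_max": 514, "n": 1960, "months": "7-10",    "alpha": 6.1971,  "beta": 1.2303, "r2": 0.976, "residual_se": 12.581, "method": "A"},
    {"x_type": "RWT", "y_type": "DWT", "x_min": 70, "x_max": 514, "y_min": 93, "y_max": 637, "n": 1960, "months": "7-10",    "alpha": 0.2911,  "beta": 0.7967, "r2": 0.976, "residual_se": 10.135, "method": "A"}
  ],
  "power": [
    {"x_type": "SFL", "y_type": "RWT",   "standardized": true,  "x_min": 53,  "x_max": 353, "y_min": 4,  "y_max": 637, "n": 51204, "months": "1-12",     "alpha": 1.77e-05, "beta": 3.0013, "residual_se": 30.651, "method": "B"},
    {"x_type": "CFL", "y_type": "RWT",   "standardized": false, "x_min": 56,  "x_max": 338, "y_min": 4,  "y_max": 637, "n": 2977,  "months": "3, 6-10",  "alpha": 4.94e-05, "beta": 2.8094, "residual_se": 32.625, "method": "C"},
    {"x_type": "CFL", "y_type": "DWT",   "standardized": false, "x_min": 127, "x_max": 366, "y_min": 25, "y_max": 514, "n": 49344, "months": "1-12",     "alpha": 8.31e-06, "beta": 3.0780, "residual_se": 24.750, "method": "C"},
    {"x_type": "SFL", "y_type": "GGTWT", "standardized": false, "x_min": 92,  "x_max": 289, "y_min": 11, "y_max": 403, "n": 2324,  "months": "1-3, 9-12","alpha": 1.27e-05, "beta": 3.0491, "residual_se": 18.242, "method": "C"}
  ]
}
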