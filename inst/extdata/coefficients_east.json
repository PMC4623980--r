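{
  "stock": "EAST",
  "description": "Published biometric relationships for the Eastern Atlantic and Mediterranean bluefin tuna stock, stored verbatim. Linear rows: y = alpha + beta * x. Power rows: y = alpha * x^beta. Method A: robust linear fit; B: CV-weighted nonlinear fit; C: Gauss-Newton nonlinear fit. Lengths cm, weights kg.",
  "linear": [
    {"x_type": "SFL",   "y_type": "LD1",    "x_min": 56,  "x_max": 300, "y_min": 17,  "y_max": 71,  "n": 636, "months": "2-8, 10, 11", "alpha": 5.6891,  "beta": 0.2543, "r2": 0.978, "residual_se": 2.052, "method": "A"},
    {"x_type": "SFL",   "y_type": "CFL",    "x_min": 78,  "x_max": 242, "y_min": 84,  "y_max": 252, "n": 222, "months": "6-7",         "alpha": -1.887,  "beta": 1.0507, "r2": 0.990, "residual_se": 4.121, "method": "A"},
    {"x_type": "LD1",   "y_type": "SFL",    "x_min": 17,  "x_max": 71,  "y_min": 56,  "y_max": 300, "n": 636, "months": "2-8, 10, 11", "alpha": -19.733, "beta": 3.8648, "r2": 0.978, "residual_se": 8.063, "method": "A"},
    {"x_type": "LD1",   "y_type": "CFL",    "x_min": 24,  "x_max": 71,  "y_min": 84,  "y_max": 283, "n": 312, "months": "5-7",         "alpha": -27.832, "beta": 4.1273, "r2": 0.964, "residual_se": 8.839, "method": "A"},
    {"x_type": "CFL",   "y_type": "LD1",    "x_min": 84,  "x_max": 283, "y_min": 24,  "y_max": 71,  "n": 312, "months": "5-7",         "alpha": 7.9182,  "beta": 0.2355, "r2": 0.964, "residual_se": 2.116, "method": "A"},
    {"x_type": "CFL",   "y_type": "SFL",    "x_min": 84,  "x_max": 252, "y_min": 78,  "y_max": 242, "n": 222, "months": "6-7",         "alpha": 2.9457,  "beta": 0.9442, "r2": 0.990, "residual_se": 3.886, "method": "A"},
    {"x_type": "CFL",   "y_type": "HeadL",  "x_min": 84,  "x_max": 284, "y_min": 22,  "y_max": 74,  "n": 306, "months": "5, 7",        "alpha": 4.4041,  "beta": 0.2242, "r2": 0.865, "residual_se": 3.048, "method": "A"},
    {"x_type": "CFL",   "y_type": "PreopL", "x_min": 153, "x_max": 284, "y_min": 33,  "y_max": 74,  "n": 294, "months": "5",           "alpha": 1.0934,  "beta": 0.1892, "r2": 0.646, "residual_se": 3.100, "method": "A"},
    {"x_type": "HeadL", "y_type": "PreopL", "x_min": 38,  "x_max": 74,  "y_min": 33,  "y_max": 74,  "n": 294, "months": "5",           "alpha": -2.2179, "beta": 0.8358, "r2": 0.783, "residual_se": 2.428, "method": "A"},
    {"x_type": "RWT",   "y_type": "GWT",    "x_min": 0.3, "x_max": 370, "y_min": 0.3, "y_max": 358, "n": 236, "months": "5-11",        "alpha": -0.2169, "beta": 0.9540, "r2": 1.000, "residual_se": 1.090, "method": "A"},
    {"x_type": "RWT",   "y_type": "GGWT",   "x_min": 3,   "x_max": 300, "y_min": 2.8, "y_max": 239, "n": 187, "months": "5-8, 10",     "alpha": 1.2985,  "beta": 0.7421, "r2": 0.991, "residual_se": 5.918, "method": "A"},
    {"x_type": "GGWT",  "y_type": "RWT",    "x_min": 2.8, "x_max": 239, "y_min": 3,   "y_max": 300, "n": 187, "months": "5-8, 10",     "alpha": -1.6151, "beta": 1.3373, "r2": 0.991, "residual_se": 7.812, "method": "A"},
    {"x_type": "GWT",   "y_type": "RWT",    "x_min": 0.3, "x_max": 358, "y_min": 0.3, "y_max": 370, "n": 236, "months": "5-11",        "alpha": 0.2312,  "beta": 1.0479, "r2": 1.000, "residual_se": 1.140, "method": "A"}
  ],
  "power": [
    {"x_type": "SFL", "y_type": "RWT",   "standardized": true,  "x_min": 27, "x_max": 300, "y_min": 0.25, "y_max": 513, "n": 74272, "months": "1-12",       "alpha": 3.51e-05, "beta": 2.8785, "residual_se": 15.965, "method": "B"},
    {"x_type": "SFL", "y_type": "GGTWT", "standardized": false, "x_min": 75, "x_max": 281, "y_min": 8,    "y_max": 362, "n": 8034,  "months": "1, 8-12",    "alpha": 4.59e-05, "beta": 2.8077, "residual_se": 13.407, "method": "C"},
    {"x_type": "SFL", "y_type": "GGWT",  "standardized": false, "x_min": 55, "x_max": 289, "y_min": 2.8,  "y_max": 385, "n": 3469,  "months": "1-12",       "alpha": 1.07e-04, "beta": 2.6301, "residual_se": 14.249, "method": "C"},
    {"x_type": "CFL", "y_type": "GGWT",  "standardized": false, "x_min": 94, "x_max": 289, "y_min": 10,   "y_max": 338, "n": 4962,  "months": "4-8",        "alpha": 2.55e-05, "beta": 2.8938, "residual_se": 15.357, "method": "C"},
    {"x_type": "LD1", "y_type": "GGWT",  "standardized": false, "x_min": 29, "x_max": 76,  "y_min": 20,   "y_max": 350, "n": 2044,  "months": "5-7, 9",     "alpha": 3.85e-03, "beta": 2.6211, "residual_se": 21.820, "method": "C"},
    {"x_type": "LD1", "y_type": "RWT",   "standardized": false, "x_min": 17, "x_max": 79,  "y_min": 3,    "y_max": 425, "n": 2796,  "months": "2-8, 10-11", "alpha": 1.12e-03, "beta": 2.9180, "residual_se": 20.019, "method": "C"}
  ]
}
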