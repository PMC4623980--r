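{
  "description": "Published monthly weight-length coefficients for Atlantic bluefin tuna: RWT_stdM = alpha * SFL_std^beta_m, SFL in cm, RWT in kg. Stored verbatim; note the monthly alpha differs in the fourth digit from the annual CV-weighted alpha for the East (3.508E-05 vs 3.51E-05) and the West (1.771E-05 vs 1.77E-05), exactly as printed.",
  "months": ["January", "February", "March", "April", "May", "June",
             "July", "August", "September", "October", "November", "December"],
  "west": {
    "alpha": 1.771e-05,
    "beta": [2.99789075, 3.00292688, 3.00833823, 3.01618530, 2.99883106, 2.98858373,
             2.99247363, 2.99823761, 3.00172394, 3.00774859, 3.00493806, 2.99596985]
  },
  "east": {
    "alpha": 3.508e-05,
    "beta": [2.87767028, 2.87585971, 2.87549667, 2.87961024, 2.88691388, 2.88309179,
             2.87153307, 2.87200195, 2.87577309, 2.87633165, 2.87716283, 2.87529487]
  }
}
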