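{
  "version": "1.0",
  "icl_summation": {
    "standard": {
      "slope": 0.835,
      "intercept": 0.161,
      "input_unit": "clo",
      "fitted_on": "ISO 9920 summation convention (not fitted on this wardrobe)"
    },
    "incident": {
      "slope": 0.835,
      "intercept": 0.311,
      "input_unit": "clo",
      "fitted_on": "incident (turnout) ensembles, intercept-adjusted standard slope"
    },
    "ou": {
      "slope": 0.975,
      "intercept": -0.194,
      "input_unit": "clo",
      "fitted_on": "operational-uniform ensembles, ordinary least squares"
    }
  },
  "fcl_estimation": {
    "modern_western": {
      "slope": 1.599,
      "intercept": 1.01,
      "input_unit": "si",
      "fitted_on": "modern Western clothing database"
    },
    "firefighter": {
      "slope": 0.2314,
      "intercept": 1.02,
      "input_unit": "clo",
      "r_squared": 0.978,
      "fitted_on": "firefighter wardrobe ensembles"
    }
  }
}
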