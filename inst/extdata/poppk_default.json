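{
  "_comment": "Default two-compartment meropenem population-PK parameters (typical critically-ill adult values). Replace with published estimates by editing this file.",
  "cl_pop": 12.5,
  "v1_pop": 10.5,
  "q": 15,
  "v2_pop": 12,
  "clcr_ref": 100,
  "wt_ref": 73,
  "alb_ref": 2.5,
  "nonrenal_fraction": 0.2,
  "clcr_breakpoint": 100,
  "slope_ratio": 1,
  "wt_exponent": 0.75,
  "alb_slope": -0.3,
  "omega": {"cl": 0.3, "v1": 0.25, "q": 0.3, "v2": 0.25},
  "residual_prop_sd": 0.2,
  "residual_add_sd": 0.5
}
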