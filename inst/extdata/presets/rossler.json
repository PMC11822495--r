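{
  "system": "rossler",
  "gain": 0.0219, "offset": 0.0073,
  "v_min": -0.21, "v_max": 0.21,
  "lp_cutoff": null, "freq_shift": 0, "noise_sd": 0.005
}
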