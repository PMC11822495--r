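{
  "system": "logistic",
  "surrogate": "logistic",
  "otl": {"theta": 0.5, "tau_min": 0.1},
  "seed": 1,
  "deposited_dir": null
}
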