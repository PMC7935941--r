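{
  "synth_rate": 1e-06,
  "synth_stop": 24,
  "k_h": 1,
  "protease_onset": 17,
  "protease_conc": 5e-08,
  "v_active": 13200,
  "v_inactive": 220
}
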