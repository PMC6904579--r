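{
  "width": 0.3945,
  "length": 0.789,
  "fillet_front": 0.02367,
  "fillet_side": 0.03156,
  "h1": 0.232755,
  "setback_post": 0.041028,
  "setback_ant": 0.03945,
  "h1_ant": 0.18936,
  "apex_y": 0.74955,
  "height": 0.45762,
  "tip_y": 0.82845,
  "tip_z": 0.44184,
  "under_y": 0.56808,
  "under_z": 0.35505,
  "xz_w_mid": 0.32,
  "xz_t_mid": 0.35,
  "xz_w_tip": 0.12,
  "species": "Chiton cumingsii"
}
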