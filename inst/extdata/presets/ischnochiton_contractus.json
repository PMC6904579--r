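{
  "width": 0.24284,
  "length": 0.467,
  "fillet_front": 0.01401,
  "fillet_side": 0.01868,
  "h1": 0.12609,
  "setback_post": 0.12609,
  "setback_ant": 0.11675,
  "h1_ant": 0.11208,
  "apex_y": 0.49035,
  "height": 0.25218,
  "tip_y": 0.58375,
  "tip_z": 0.24284,
  "under_y": 0.44365,
  "under_z": 0.1868,
  "xz_w_mid": 0.32,
  "xz_t_mid": 0.32,
  "xz_w_tip": 0.11,
  "species": "Ischnochiton contractus"
}
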