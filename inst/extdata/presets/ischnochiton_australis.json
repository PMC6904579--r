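{
  "width": 0.3971,
  "length": 0.722,
  "fillet_front": 0.02166,
  "fillet_side": 0.02888,
  "h1": 0.18772,
  "setback_post": 0.3249,
  "setback_ant": 0.30324,
  "h1_ant": 0.17328,
  "apex_y": 0.9025,
  "height": 0.4693,
  "tip_y": 1.1191,
  "tip_z": 0.37544,
  "under_y": 0.8303,
  "under_z": 0.2527,
  "xz_w_mid": 0.3,
  "xz_t_mid": 0.35,
  "xz_w_tip": 0.1,
  "species": "Ischnochiton australis"
}
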