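{
  "width": 0.2895,
  "length": 0.579,
  "fillet_front": 0.01737,
  "fillet_side": 0.02316,
  "h1": 0.1158,
  "setback_post": 0.08106,
  "setback_ant": 0.07527,
  "h1_ant": 0.09843,
  "apex_y": 0.6948,
  "height": 0.2895,
  "tip_y": 0.83955,
  "tip_z": 0.24318,
  "under_y": 0.55005,
  "under_z": 0.15054,
  "xz_w_mid": 0.32,
  "xz_t_mid": 0.3,
  "xz_w_tip": 0.12,
  "species": "Ischnochiton lentiginosus"
}
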