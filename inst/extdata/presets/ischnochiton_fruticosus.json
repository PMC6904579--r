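{
  "width": 0.323,
  "length": 0.646,
  "fillet_front": 0.01938,
  "fillet_side": 0.02584,
  "h1": 0.1292,
  "setback_post": 0.108528,
  "setback_ant": 0.0969,
  "h1_ant": 0.11628,
  "apex_y": 0.7106,
  "height": 0.3553,
  "tip_y": 0.8721,
  "tip_z": 0.323,
  "under_y": 0.5814,
  "under_z": 0.20026,
  "xz_w_mid": 0.32,
  "xz_t_mid": 0.3,
  "xz_w_tip": 0.12,
  "species": "Ischnochiton fruticosus"
}
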