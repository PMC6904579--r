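{
  "width": 0.204,
  "length": 0.425,
  "fillet_front": 0.01275,
  "fillet_side": 0.017,
  "h1": 0.085,
  "setback_post": 0.04148,
  "setback_ant": 0.03825,
  "h1_ant": 0.0765,
  "apex_y": 0.4675,
  "height": 0.25075,
  "tip_y": 0.52275,
  "tip_z": 0.227375,
  "under_y": 0.357,
  "under_z": 0.146625,
  "xz_w_mid": 0.79,
  "xz_t_mid": 0.45,
  "xz_w_tip": 0.62,
  "species": "Rhyssoplax canariensis"
}
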