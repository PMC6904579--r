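{
  "width": 0.39312,
  "length": 0.819,
  "fillet_front": 0.02457,
  "fillet_side": 0.03276,
  "h1": 0.1638,
  "setback_post": 0.090909,
  "setback_ant": 0.0819,
  "h1_ant": 0.14742,
  "apex_y": 0.85995,
  "height": 0.42588,
  "tip_y": 0.9828,
  "tip_z": 0.40131,
  "under_y": 0.68796,
  "under_z": 0.27846,
  "xz_w_mid": 0.32,
  "xz_t_mid": 0.3,
  "xz_w_tip": 0.12,
  "species": "Radsia barnesii"
}
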