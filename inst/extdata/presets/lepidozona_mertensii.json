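{
  "width": 0.2112,
  "length": 0.384,
  "fillet_front": 0.01152,
  "fillet_side": 0.01536,
  "h1": 0.0768,
  "setback_post": 0.0279552,
  "setback_ant": 0.02496,
  "h1_ant": 0.0576,
  "apex_y": -0.2112,
  "height": 0.16896,
  "tip_y": 0.3264,
  "tip_z": 0.16128,
  "under_y": 0.25344,
  "under_z": 0.12288,
  "xz_w_mid": 0.24,
  "xz_t_mid": 0.35,
  "xz_w_tip": 0.1,
  "species": "Lepidozona mertensii"
}
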