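{
  "width": 5,
  "length": 10,
  "fillet_front": 0.3,
  "fillet_side": 0.4,
  "h1": 4.1,
  "setback_post": 1.91,
  "setback_ant": 1.7,
  "h1_ant": 3.8,
  "apex_y": 10.5,
  "height": 8.5,
  "tip_y": 12.5,
  "tip_z": 8,
  "under_y": 9.5,
  "under_z": 5.8,
  "xz_w_mid": 0.62,
  "xz_t_mid": 0.35,
  "xz_w_tip": 0.6,
  "species": "armor prototype"
}
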