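{
  "width": 0.54,
  "length": 1.08,
  "fillet_front": 0.0324,
  "fillet_side": 0.0432,
  "h1": 0.216,
  "setback_post": 0.11016,
  "setback_ant": 0.0972,
  "h1_ant": 0.1944,
  "apex_y": 1.188,
  "height": 0.6156,
  "tip_y": 1.3284,
  "tip_z": 0.5616,
  "under_y": 0.9072,
  "under_z": 0.3672,
  "xz_w_mid": 0.32,
  "xz_t_mid": 0.3,
  "xz_w_tip": 0.12,
  "species": "Rhyssoplax polita"
}
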