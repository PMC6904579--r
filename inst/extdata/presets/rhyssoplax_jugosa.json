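{
  "width": 0.34224,
  "length": 0.744,
  "fillet_front": 0.02232,
  "fillet_side": 0.02976,
  "h1": 0.15624,
  "setback_post": 0.0631656,
  "setback_ant": 0.0558,
  "h1_ant": 0.13392,
  "apex_y": 0.7812,
  "height": 0.40176,
  "tip_y": 0.8928,
  "tip_z": 0.38688,
  "under_y": 0.61008,
  "under_z": 0.27528,
  "xz_w_mid": 0.28,
  "xz_t_mid": 0.3,
  "xz_w_tip": 0.11,
  "species": "Rhyssoplax jugosa"
}
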