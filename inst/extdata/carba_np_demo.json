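{
  "bounds": [40, 40],
  "model": {},
  "magnet": {"position": [1, 1]},
  "droplets": [
    {"id": "solutionA_test", "center": [8, 28], "volume": 10,
     "color": [220, 40, 50], "props": {"imipenem": true}},
    {"id": "lysate_test", "center": [18, 28], "volume": 10,
     "props": {"cpe": true}}
  ],
  "clusters": [
    {"id": "particles_test", "host": "solutionA_test", "volume": 1.5}
  ],
  "sets": [
    {"id": "set_test", "center": [30, 28], "radius": 1}
  ]
}
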