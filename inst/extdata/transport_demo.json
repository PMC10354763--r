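{
  "bounds": [40, 40],
  "model": {"k_mag": 20, "k_exit": 8, "k_drag": 6,
            "set_factor": 0.5, "power_gain": 1.5},
  "magnet": {"position": [1, 1], "power_level": "default", "lag": 0},
  "droplets": [
    {"id": "d1", "center": [10, 20], "volume": 10}
  ],
  "clusters": [
    {"id": "p1", "host": "d1", "volume": 0.3}
  ],
  "sets": []
}
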