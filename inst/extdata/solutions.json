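[
  {"name": "pure_water", "osmolality_osm": 0, "m_K_per_osm": 1.858},
  {"name": "1xPBS", "osmolality_osm": 0.2853, "m_K_per_osm": 1.858},
  {"name": "1xPBS_nominal", "osmolality_osm": 0.3, "m_K_per_osm": 1.858},
  {"name": "10xPBS", "osmolality_osm": 2.853, "m_K_per_osm": 1.858},
  {"name": "glycerol_1M_1xPBS", "osmolality_osm": 1.2917, "m_K_per_osm": 1.858}
]
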