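[
  {"name": "India", "population": 1210854977, "level": "country"},
  {"name": "Uttar Pradesh", "population": 199812341, "level": "state", "parent": "India"},
  {"name": "Agra", "population": 1585704, "level": "city", "parent": "Uttar Pradesh"},
  {"name": "Aligarh", "population": 874408, "level": "city", "parent": "Uttar Pradesh"},
  {"name": "Allahabad", "population": 1117094, "level": "city", "parent": "Uttar Pradesh"},
  {"name": "Bareilly", "population": 903668, "level": "city", "parent": "Uttar Pradesh"},
  {"name": "Benares", "population": 1201815, "level": "city", "parent": "Uttar Pradesh"},
  {"name": "Gorakhpur", "population": 673446, "level": "city", "parent": "Uttar Pradesh"},
  {"name": "Jhansi", "population": 507293, "level": "city", "parent": "Uttar Pradesh"},
  {"name": "Kanpur", "population": 2765348, "level": "city", "parent": "Uttar Pradesh"},
  {"name": "Lucknow", "population": 2815601, "level": "city", "parent": "Uttar Pradesh"},
  {"name": "Noida", "population": 642381, "level": "city", "parent": "Uttar Pradesh"}
]
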