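{
  "pelvis": {
    "required": ["RASIS", "LASIS", "RPSIS", "LPSIS"],
    "origin": ["RASIS", "LASIS"],
    "primary": {"axis": "z", "from": ["LASIS"], "to": ["RASIS"]},
    "secondary": {"axis": "x", "from": ["RPSIS", "LPSIS"], "to": ["RASIS", "LASIS"]}
  },
  "thigh": {
    "required": ["HIP", "KNEE_LAT", "KNEE_MED"],
    "origin": ["KNEE_LAT", "KNEE_MED"],
    "primary": {"axis": "y", "from": ["KNEE_LAT", "KNEE_MED"], "to": ["HIP"]},
    "secondary": {"axis": "z", "from": ["KNEE_MED"], "to": ["KNEE_LAT"]}
  },
  "shank": {
    "required": ["KNEE_LAT", "KNEE_MED", "ANK_LAT", "ANK_MED"],
    "origin": ["ANK_LAT", "ANK_MED"],
    "primary": {"axis": "y", "from": ["ANK_LAT", "ANK_MED"], "to": ["KNEE_LAT", "KNEE_MED"]},
    "secondary": {"axis": "z", "from": ["ANK_MED"], "to": ["ANK_LAT"]}
  },
  "foot": {
    "required": ["HEEL", "TOE", "MT1", "MT5"],
    "origin": ["HEEL"],
    "primary": {"axis": "x", "from": ["HEEL"], "to": ["TOE"]},
    "secondary": {"axis": "z", "from": ["MT1"], "to": ["MT5"]}
  }
}
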