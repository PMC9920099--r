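{
  "rows": ["FC", "C", "CP", "P"],
  "lines": [5, 3, 1, 2, 4, 6],
  "electrodes": {
    "FC5": {"row": "FC", "line": 5},
    "FC3": {"row": "FC", "line": 3},
    "FC1": {"row": "FC", "line": 1},
    "FC2": {"row": "FC", "line": 2},
    "FC4": {"row": "FC", "line": 4},
    "FC6": {"row": "FC", "line": 6},
    "C5":  {"row": "C",  "line": 5},
    "C3":  {"row": "C",  "line": 3},
    "C1":  {"row": "C",  "line": 1},
    "C2":  {"row": "C",  "line": 2},
    "C4":  {"row": "C",  "line": 4},
    "C6":  {"row": "C",  "line": 6},
    "CP5": {"row": "CP", "line": 5},
    "CP3": {"row": "CP", "line": 3},
    "CP1": {"row": "CP", "line": 1},
    "CP2": {"row": "CP", "line": 2},
    "CP4": {"row": "CP", "line": 4},
    "CP6": {"row": "CP", "line": 6},
    "P5":  {"row": "P",  "line": 5},
    "P3":  {"row": "P",  "line": 3},
    "P1":  {"row": "P",  "line": 1},
    "P2":  {"row": "P",  "line": 2},
    "P4":  {"row": "P",  "line": 4},
    "P6":  {"row": "P",  "line": 6}
  }
}
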