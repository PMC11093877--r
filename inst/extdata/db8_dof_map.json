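{
  "comment": "Cyberglove sensor -> target DOF map (1-based glove channel indices). Edit to match your glove calibration/release; sensor order assumed: 1 thumb CMC rotation, 2 thumb MCP flex, 3 thumb IP flex, 4 thumb abduction, 5 index MCP flex, 6 index PIP flex, 7 middle MCP flex, 8 middle PIP flex, 9 middle-index abduction, 10 ring MCP flex, 11 ring PIP flex, 12 ring-middle abduction, 13 little MCP flex, 14 little PIP flex, 15 little-ring abduction, 16 palm arch, 17 wrist flex, 18 wrist abduction.",
  "dof_map": {
    "thumb_flex": 2,
    "thumb_abd": 4,
    "index_flex": 5,
    "middle_flex": 7,
    "ring_flex": 10,
    "little_flex": 13
  }
}
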