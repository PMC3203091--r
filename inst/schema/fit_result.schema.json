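{
  "$schema": "http://json-schema.org/draft-07/schema#",
  "title": "hybcoal fit result",
  "type": "object",
  "required": ["gamma", "t1", "t2", "t3", "lnL", "cycles", "converged", "boundary"],
  "properties": {
    "gamma": {"type": "number", "minimum": 0, "maximum": 1},
    "t1": {"type": "number", "minimum": 0},
    "t2": {"type": "number", "minimum": 0},
    "t3": {"type": "number", "minimum": 0},
    "lnL": {"type": "number"},
    "cycles": {"type": "integer", "minimum": 1},
    "converged": {"type": "boolean"},
    "boundary": {"type": "object"}
  }
}
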