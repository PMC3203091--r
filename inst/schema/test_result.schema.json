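{
  "$schema": "http://json-schema.org/draft-07/schema#",
  "title": "hybcoal likelihood-ratio test result",
  "type": "object",
  "required": ["delta", "p_value", "gamma_hat", "lnL_alt", "lnL_null"],
  "properties": {
    "delta": {"type": "number", "minimum": 0},
    "p_value": {"type": "number", "exclusiveMinimum": 0, "maximum": 1},
    "gamma_hat": {"type": "number", "minimum": 0, "maximum": 1},
    "t1_hat": {"type": "number"},
    "t2_hat": {"type": "number"},
    "t3_hat": {"type": "number"},
    "lnL_alt": {"type": "number"},
    "lnL_null": {"type": "number"}
  }
}
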