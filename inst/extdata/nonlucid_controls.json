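{
  "per_team": {"USA": 32, "Germany": 347, "Netherlands": 0},
  "outcomes": {"correct": 1, "incorrect": 1, "ambiguous": 11, "no_response": 366},
  "sham": {"markers": 28, "responses": 0}
}
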