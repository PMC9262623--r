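{
  "subcommand": "simulate",
  "parameters": {
    "n": 8,
    "mode": "aa"
  },
  "reference_checksum": "ad6c685f9dccca418ffadaf1684d21c2",
  "seed": 3,
  "warnings_summary": [],
  "timestamp": "2026-09-28T13:00:51+0000"
}
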