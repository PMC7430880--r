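{
  "title": "simvalid validity report",
  "required": ["provenance", "tasks", "notes"],
  "provenance_required": ["seed", "alpha", "scenario", "config_hash", "package"],
  "task_required": ["selected", "construct", "composite", "weights", "scores", "cutoffs"],
  "task_optional_when_empty": ["composite", "weights", "scores", "cutoffs"]
}
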