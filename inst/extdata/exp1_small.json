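{
  "experiment": 1,
  "n_participants": 4,
  "blocks_per_participant": 3,
  "delay_blocks": 3,
  "seed": 11,
  "traces": false,
  "model": 1
}
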