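{
  "experiment": 2,
  "n_participants": 6,
  "blocks_per_participant": 10,
  "delay_blocks": 3,
  "seed": 5,
  "traces": false,
  "model": 1,
  "n_validation_trials": 10
}
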