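# Scaled-down study replica for demos and smoke runs: 2 subjects per arm,
# 2 training sessions, reduced trial counts. Protocol-faithful defaults
# (20 sessions, full trial counts, 20 per arm) apply when a field is
# omitted; see ?study_config.
n_per_arm: 2
plan:
  n_sessions: 2
  sessions_per_week: 5
  programs_per_session: {abm: 2, act: 2, nback: 2, matrix: 2}
tasks:
  abm: {n_main: 20, n_practice: 4}
  act: {n_main: 24}
  nback: {n_blocks: 2, block_size: 10}
  matrix: {n_trials: 10}
  bart: {n_balloons: 30}
write_training_logs: true
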