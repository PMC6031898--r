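# Example simulated-respondent parameters; see ?agent_params.
ddt:
  k_true: 0.05        # per-day hyperbolic discount rate
  choice_noise: 0     # 0 = deterministic threshold chooser
igt:
  alpha: 0.2          # delta-rule learning rate
  tau: 10             # softmax temperature
bart:
  pump_threshold: 64  # cash out after this many pumps
responder:
  p_correct: 0.95
  latency_meanlog: 6.2
  latency_sdlog: 0.25
  category_effect_ms: 0
  p_timeout: 0
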