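# Small simulated-experiment plan (see read_plan()); flat keys combine
# experiment_plan(), condition_spec(), agent_params() and pair_scenario()
# overrides.
n_pairs: 3
days: 5
latent_days: 0
seed: 11
divider: transparent_perforated
context_cues: false
mode: paired
session_s: 300
dt_s: 0.04
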