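# Engine/maze configuration, flat keys mirroring maze_geometry(),
# engine_params() and condition_spec(). Every default is overridable.
length_cm: 120
width_cm: 40
n_lanes: 2
zone_bounds_cm: [40, 80]
hysteresis_cm: 0
max_mismatch_s: 10
max_rewarded_trials: 20
max_session_s: 900
reward_volume_ul: 70
pump_duration_s: 1.5
mode: paired
divider: transparent_perforated
context_cues: false
sex: unspecified
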