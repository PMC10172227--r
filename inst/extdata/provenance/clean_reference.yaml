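# Illustrative (synthetic) provenance pack: the no-findings reference —
# everything scaled, same cohort, muscle-specific tension, tendon set from a
# kinetically calibrated optimal joint position.
schema: mtsens-provenance-v1
label: clean_reference (illustrative)
sarcomere_measured: true
fiber_scaled_to_optimal: true
uniform_optimal_sarcomere: false
pennation_scaled: true
pennation_raw_used_in_projected_pcsa: false
fiber_length_source_cohort: young_in_vivo
volume_source_cohort: young_in_vivo
specific_tension_source: same_cohort
tendon_mode: computed_at_calibrated_position
raw_pennation_deg: 10
raw_sarcomere_um: 2.65
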