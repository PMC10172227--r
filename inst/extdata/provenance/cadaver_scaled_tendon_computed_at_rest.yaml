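# Illustrative (synthetic) provenance pack: a cadaveric dataset whose fiber
# lengths and pennation angles were optimally scaled by sarcomere length, but
# whose tendon slack length was computed so that fiber optimality falls at the
# anatomical fixation position. Not a reproduction of any published table.
schema: mtsens-provenance-v1
label: cadaver_scaled_tendon_computed_at_rest (illustrative)
sarcomere_measured: true
fiber_scaled_to_optimal: true
uniform_optimal_sarcomere: true
pennation_scaled: true
pennation_raw_used_in_projected_pcsa: false
fiber_length_source_cohort: elderly_cadaver
volume_source_cohort: elderly_cadaver
specific_tension_source: uniform
tendon_mode: computed_at_measurement_position
raw_pennation_deg: 28.3
raw_sarcomere_um: 2.12
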