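# Illustrative (synthetic) provenance pack: a dataset with no sarcomere
# measurements (raw fiber lengths and pennation used as optimal values) and a
# directly measured tendon length used as the slack length.
schema: mtsens-provenance-v1
label: measured_tendon_unscaled_dataset (illustrative)
sarcomere_measured: false
fiber_scaled_to_optimal: false
uniform_optimal_sarcomere: false
pennation_scaled: false
pennation_raw_used_in_projected_pcsa: false
fiber_length_source_cohort: elderly_cadaver
volume_source_cohort: elderly_cadaver
specific_tension_source: same_cohort
tendon_mode: measured_length
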