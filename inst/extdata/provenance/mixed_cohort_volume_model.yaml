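# Illustrative (synthetic) provenance pack: a model whose muscle volumes come
# from young in-vivo imaging while fiber lengths are inherited from elderly
# cadavers, with an inherited specific tension and tendon slack length from a
# calibrated optimal position.
schema: mtsens-provenance-v1
label: mixed_cohort_volume_model (illustrative)
sarcomere_measured: true
fiber_scaled_to_optimal: true
uniform_optimal_sarcomere: true
pennation_scaled: true
pennation_raw_used_in_projected_pcsa: false
fiber_length_source_cohort: elderly_cadaver
volume_source_cohort: young_in_vivo
specific_tension_source: inherited
tendon_mode: computed_at_calibrated_position
raw_pennation_deg: 28.3
raw_sarcomere_um: 2.12
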