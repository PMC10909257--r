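name,category,pictogram_count,signal_word,amount_bracket
distilled_water,reagent,0,none,from_10_to_100
uv_spectrophotometer,instrument,NA,NA,up_to_0.1_kWh
process,occupational_hazard,NA,NA,hermetic
waste,waste,NA,NA,from_1_to_10
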