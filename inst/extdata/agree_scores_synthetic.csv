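principle,score
1_sample_treatment,0.82
2_sample_amount,0.87
3_device_positioning,0.62
4_process_steps,0.78
5_automation_miniaturization,0.82
6_derivatization,0.86
7_waste,0.64
8_analysis_throughput,0.70
9_energy,0.72
10_reagent_source,0.85
11_toxicity,0.71
12_operator_safety,0.85
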