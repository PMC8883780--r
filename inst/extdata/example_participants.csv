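participant_id,body_weight_kg,analysis_weight
P001,82,1.1
P002,64,0.9
P003,71,1.0
P004,,1.0
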