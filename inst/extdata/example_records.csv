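participant_id,day_index,food_code,grams
P001,1,BR01,105
P001,1,YO02,150
P001,2,BR03,70
P001,2,SO01,250
P002,1,BR01,140
P002,1,YO01,125
P002,2,BR02,105
P002,2,YO03,150
P003,1,BR04,70
P003,2,SO02,250
P004,1,BR01,105
P004,2,YO02,150
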