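# Synthetic example scenario: replace below-P75 foods in three groups by a
# familiar high-protein alternative from the same group. The groups and
# alternatives are illustrative fixtures, not survey-derived choices.
scenario_id: example-protein-rich
eligibility_cutoff: 1.0
replacements:
- group: bread
  alternative_food_code: BR05
- group: "yoghurt, cream desserts and pudding"
  alternative_food_code: YO04
- group: soups
  alternative_food_code: SO03
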