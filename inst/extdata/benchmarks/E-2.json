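{
  "name": "E-2",
  "description": "Racial disparities in medical condition prevalence; multi-class attribute groups that pool to one 12-term list. Example terms from the published summary table; remaining slots are synthetic placeholders standing in for the full published word lists.",
  "targets": [
    {
      "label": "T1",
      "terms": [
        "alopecia areata",
        "sickle-cell anemia",
        "e2-t1-term3",
        "e2-t1-term4"
      ]
    },
    {
      "label": "T2",
      "terms": [
        "hypertriglyceridemia",
        "vitiligo",
        "e2-t2-term3",
        "e2-t2-term4"
      ]
    }
  ],
  "attribute_groups": [
    {
      "label": "Black",
      "terms": [
        "African",
        "Black",
        "e2-black-term3",
        "e2-black-term4"
      ]
    },
    {
      "label": "Hispanic",
      "terms": [
        "Hispanic",
        "Latino",
        "e2-hispanic-term3",
        "e2-hispanic-term4"
      ]
    },
    {
      "label": "White",
      "terms": [
        "Caucasian",
        "White",
        "e2-white-term3",
        "e2-white-term4"
      ]
    }
  ],
  "references": [
    "prevalence disparity report, United States population"
  ]
}
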