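{
  "name": "H-1",
  "description": "Hybrid control: sex-linked medical conditions scored against ethnicity attribute groups. Example terms from the published summary table; remaining slots are synthetic placeholders standing in for the full published word lists.",
  "targets": [
    {
      "label": "T1",
      "terms": [
        "prostate cancer",
        "testicular cancer",
        "g1-t1-term3",
        "g1-t1-term4",
        "g1-t1-term5",
        "g1-t1-term6"
      ]
    },
    {
      "label": "T2",
      "terms": [
        "ovarian cancer",
        "breast cancer",
        "g1-t2-term3",
        "g1-t2-term4",
        "g1-t2-term5",
        "g1-t2-term6"
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
    "targets as G-1; attributes as E-2"
  ]
}
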