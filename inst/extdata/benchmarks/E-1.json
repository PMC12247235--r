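{
  "name": "E-1",
  "description": "Ethnic disparities in Finnish and Ashkenazi Jewish hereditary genetic conditions. Example terms from the published summary table; remaining slots are synthetic placeholders standing in for the full published word lists.",
  "targets": [
    {
      "label": "T1",
      "terms": [
        "Cohen syndrome",
        "Salla disease",
        "e1-t1-term3",
        "e1-t1-term4",
        "e1-t1-term5"
      ]
    },
    {
      "label": "T2",
      "terms": [
        "Bloom syndrome",
        "Tay-Sachs disease",
        "e1-t2-term3",
        "e1-t2-term4",
        "e1-t2-term5"
      ]
    }
  ],
  "attribute_groups": [
    {
      "label": "Finnish",
      "terms": [
        "Finnish",
        "Finn",
        "e1-a1-term3",
        "e1-a1-term4",
        "e1-a1-term5",
        "e1-a1-term6",
        "e1-a1-term7"
      ]
    },
    {
      "label": "Jewish",
      "terms": [
        "Ashkenazi",
        "Jewish",
        "e1-a2-term3",
        "e1-a2-term4",
        "e1-a2-term5",
        "e1-a2-term6",
        "e1-a2-term7"
      ]
    }
  ],
  "references": [
    "hereditary condition lists per published sources"
  ]
}
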