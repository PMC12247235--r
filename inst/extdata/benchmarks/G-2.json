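{
  "name": "G-2",
  "description": "Sex disparities in medical conditions with a sex ratio of >= 3:1. Example terms from the published summary table; remaining slots are synthetic placeholders standing in for the full published word lists.",
  "targets": [
    {
      "label": "T1",
      "terms": [
        "prostate cancer",
        "color blindness",
        "g2-t1-term3",
        "g2-t1-term4",
        "g2-t1-term5",
        "g2-t1-term6",
        "g2-t1-term7",
        "g2-t1-term8",
        "g2-t1-term9",
        "g2-t1-term10",
        "g2-t1-term11"
      ]
    },
    {
      "label": "T2",
      "terms": [
        "ovarian cancer",
        "osteoporosis",
        "g2-t2-term3",
        "g2-t2-term4",
        "g2-t2-term5",
        "g2-t2-term6",
        "g2-t2-term7",
        "g2-t2-term8",
        "g2-t2-term9",
        "g2-t2-term10",
        "g2-t2-term11"
      ]
    }
  ],
  "attribute_groups": [
    {
      "label": "male",
      "terms": [
        "male",
        "man",
        "boy",
        "brother",
        "he",
        "him",
        "his",
        "son"
      ]
    },
    {
      "label": "female",
      "terms": [
        "female",
        "woman",
        "girl",
        "sister",
        "she",
        "her",
        "hers",
        "daughter"
      ]
    }
  ],
  "references": [
    "gender attribute lists: WEAT-7 (Caliskan et al. 2017)"
  ]
}
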