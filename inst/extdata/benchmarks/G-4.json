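{
  "name": "G-4",
  "description": "Sex differences in adverse drug reactions (log reporting odds ratio beyond +/- 6). Example terms from the published summary table; remaining slots are synthetic placeholders standing in for the full published word lists.",
  "targets": [
    {
      "label": "T1",
      "terms": [
        "erectile dysfunction",
        "incisional hernia",
        "g4-t1-term3",
        "g4-t1-term4",
        "g4-t1-term5",
        "g4-t1-term6",
        "g4-t1-term7",
        "g4-t1-term8",
        "g4-t1-term9",
        "g4-t1-term10"
      ]
    },
    {
      "label": "T2",
      "terms": [
        "platelet disorder",
        "motor dysfunction",
        "g4-t2-term3",
        "g4-t2-term4",
        "g4-t2-term5",
        "g4-t2-term6",
        "g4-t2-term7",
        "g4-t2-term8",
        "g4-t2-term9",
        "g4-t2-term10"
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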