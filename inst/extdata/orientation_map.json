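{
  "comment": "Six-level party-orientation map: levels 1..6 are extreme-left, left, center-left, center, center-right, right. Votes on extreme-left and left parties count as extreme negative; center-right and right as extreme positive.",
  "n_levels": 6,
  "positive": [4, 5, 6],
  "extreme_positive": [5, 6],
  "negative": [1, 2, 3],
  "extreme_negative": [1, 2]
}
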