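{
  "method": "two_way",
  "q": 0.05,
  "factors": {
    "levels": [2, 2, 3],
    "names": ["sex", "smoker", "stage"],
    "labels": [["female", "male"], ["no", "yes"], ["I", "II", "III"]]
  },
  "seed": 20260929
}
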