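{
  "schema": "seqguide-tree/1",
  "max_depth": 3,
  "degenerate": false,
  "comment": "SYNTHETIC stand-in for the published human single-end CTCF ChIP-seq guideline tree: the published tree needs two splits, on unmapped-read percentage and distal-intergenic localization, to reach 100% training accuracy, but its thresholds and node counts are not printed; the values below are invented to reproduce the structure only.",
  "root": {
    "samples": 16,
    "samples_by_class": [10, 6],
    "predicted_class": "high",
    "gini": 0.46875,
    "leaf": false,
    "feature": "MAP_SE_no_mapping",
    "threshold": 5.2,
    "left": {
      "samples": 12,
      "samples_by_class": [10, 2],
      "predicted_class": "high",
      "gini": 0.277777777777778,
      "leaf": false,
      "feature": "LOC_Distal_Intergenic",
      "threshold": 30.5,
      "left": {
        "samples": 10,
        "samples_by_class": [10, 0],
        "predicted_class": "high",
        "gini": 0,
        "leaf": true
      },
      "right": {
        "samples": 2,
        "samples_by_class": [0, 2],
        "predicted_class": "low",
        "gini": 0,
        "leaf": true
      }
    },
    "right": {
      "samples": 4,
      "samples_by_class": [0, 4],
      "predicted_class": "low",
      "gini": 0,
      "leaf": true
    }
  }
}
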