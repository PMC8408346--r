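{
  "schema": "seqguide-tree/1",
  "max_depth": 3,
  "degenerate": false,
  "comment": "Guideline tree for human single-end H3K4me1 ChIP-seq files, transcribed from the published figure (30 training files, 100% training accuracy).",
  "root": {
    "samples": 30,
    "samples_by_class": [18, 12],
    "predicted_class": "high",
    "gini": 0.48,
    "leaf": false,
    "feature": "MAP_SE_multiple",
    "threshold": 15.68,
    "left": {
      "samples": 9,
      "samples_by_class": [2, 7],
      "predicted_class": "low",
      "gini": 0.345679012345679,
      "leaf": false,
      "feature": "LOC_Other_Intron",
      "threshold": 34.072,
      "left": {
        "samples": 7,
        "samples_by_class": [0, 7],
        "predicted_class": "low",
        "gini": 0,
        "leaf": true
      },
      "right": {
        "samples": 2,
        "samples_by_class": [2, 0],
        "predicted_class": "high",
        "gini": 0,
        "leaf": true
      }
    },
    "right": {
      "samples": 21,
      "samples_by_class": [16, 5],
      "predicted_class": "high",
      "gini": 0.362811791383220,
      "leaf": false,
      "feature": "TSS_+2500",
      "threshold": 2.466,
      "left": {
        "samples": 13,
        "samples_by_class": [13, 0],
        "predicted_class": "high",
        "gini": 0,
        "leaf": true
      },
      "right": {
        "samples": 8,
        "samples_by_class": [3, 5],
        "predicted_class": "low",
        "gini": 0.46875,
        "leaf": false,
        "feature": "TSS_+500",
        "threshold": 3.701,
        "left": {
          "samples": 5,
          "samples_by_class": [0, 5],
          "predicted_class": "low",
          "gini": 0,
          "leaf": true
        },
        "right": {
          "samples": 3,
          "samples_by_class": [3, 0],
          "predicted_class": "high",
          "gini": 0,
          "leaf": true
        }
      }
    }
  }
}
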