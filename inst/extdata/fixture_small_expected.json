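{
  "config": {
    "filter": {
      "minAbundance": 5,
      "minSamples": 1
    },
    "discretize": {
      "highFraction": 0.25,
      "lowFraction": 0.25
    },
    "metrics": {
      "corrThreshold": 0.5,
      "duoThreshold": 0.65
    }
  },
  "keptTranscripts": ["t1", "t2", "t4", "t5", "t6", "t7", "t8"],
  "thresholds": {
    "lower": 0.25,
    "upper": 0.9
  },
  "states": ["NLNNHL", "LNNLNH", "NNNHNH", "LNNNNH", "HNNNNL", "NNNNNH", "LNLHNL", "NNNMHL", "LHLHHL"],
  "duo": [
    {
      "featureA": "t1",
      "featureB": "traitA",
      "components": {
        "HH": 0.600888888888889,
        "LL": 0.508444444444445,
        "HL": 0,
        "LH": 0
      },
      "n": 5
    },
    {
      "featureA": "t1",
      "featureB": "traitB",
      "components": {
        "HH": 0.395061728395062,
        "LL": 0.345679012345679,
        "HL": 0,
        "LH": 0.345679012345679
      },
      "n": 6
    },
    {
      "featureA": "t2",
      "featureB": "traitA",
      "components": {
        "HH": 0,
        "LL": 0,
        "HL": 0.600888888888889,
        "LH": 0
      },
      "n": 5
    },
    {
      "featureA": "t2",
      "featureB": "traitB",
      "components": {
        "HH": 0,
        "LL": 0.345679012345679,
        "HL": 0.395061728395062,
        "LH": 0.345679012345679
      },
      "n": 6
    },
    {
      "featureA": "t4",
      "featureB": "traitA",
      "components": {
        "HH": 0,
        "LL": 0,
        "HL": 0.600888888888889,
        "LH": 0
      },
      "n": 5
    },
    {
      "featureA": "t4",
      "featureB": "traitB",
      "components": {
        "HH": 0.345679012345679,
        "LL": 0,
        "HL": 0.345679012345679,
        "LH": 0
      },
      "n": 6
    },
    {
      "featureA": "t5",
      "featureB": "traitA",
      "components": {
        "HH": 0,
        "LL": 0,
        "HL": 0.600888888888889,
        "LH": 0
      },
      "n": 5
    },
    {
      "featureA": "t5",
      "featureB": "traitB",
      "components": {
        "HH": 0,
        "LL": 0.395061728395062,
        "HL": 0.395061728395062,
        "LH": 0
      },
      "n": 6
    },
    {
      "featureA": "t6",
      "featureB": "traitA",
      "components": {
        "HH": 0,
        "LL": 0.600888888888889,
        "HL": 0,
        "LH": 0
      },
      "n": 5
    },
    {
      "featureA": "t6",
      "featureB": "traitB",
      "components": {
        "HH": 0,
        "LL": 0.395061728395062,
        "HL": 0.395061728395062,
        "LH": 0
      },
      "n": 6
    },
    {
      "featureA": "t7",
      "featureB": "traitA",
      "components": {
        "HH": 0,
        "LL": 0,
        "HL": 0.600888888888889,
        "LH": 0
      },
      "n": 5
    },
    {
      "featureA": "t7",
      "featureB": "traitB",
      "components": {
        "HH": 0,
        "LL": 0,
        "HL": 0.395061728395062,
        "LH": 0
      },
      "n": 6
    },
    {
      "featureA": "t8",
      "featureB": "traitA",
      "components": {
        "HH": 0,
        "LL": 0.416,
        "HL": 0,
        "LH": 0
      },
      "n": 5
    },
    {
      "featureA": "t8",
      "featureB": "traitB",
      "components": {
        "HH": 0.395061728395062,
        "LL": 0.888888888888889,
        "HL": 0,
        "LH": 0
      },
      "n": 6
    }
  ],
  "counts": {
    "transcriptsIn": 8,
    "transcriptsAfterFilter": 7,
    "traits": 2,
    "edges": {
      "pearson": 4,
      "spearman": 4,
      "duo": 1
    }
  }
}
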