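{
  "TOYV1-1*01": {
    "frame_offset": 0,
    "regions": {
      "FR1": [0, 25],
      "CDR1": [25, 33],
      "FR2": [33, 50],
      "CDR2": [50, 58],
      "FR3": [58, 100]
    }
  },
  "TOYV2-1*01": {
    "frame_offset": 0,
    "regions": {
      "FR1": [0, 25],
      "CDR1": [25, 33],
      "FR2": [33, 50],
      "CDR2": [50, 58],
      "FR3": [58, 100]
    }
  },
  "TOYV3-1*01": {
    "frame_offset": 0,
    "regions": {
      "FR1": [0, 25],
      "CDR1": [25, 33],
      "FR2": [33, 50],
      "CDR2": [50, 58],
      "FR3": [58, 100]
    }
  }
}
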