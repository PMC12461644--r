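{
  "version": 1,
  "modality_map": {
    "MR": "magnetic resonance imaging",
    "MRI": "magnetic resonance imaging",
    "magnetic resonance imaging": "magnetic resonance imaging",
    "CT": "computed tomography",
    "computed tomography": "computed tomography",
    "CBCT": "cone beam computed tomography",
    "cone beam computed tomography": "cone beam computed tomography"
  },
  "lowercase_tokens": ["Organ", "Plane"],
  "numeric_digits": {
    "MagneticFieldStrength": 1,
    "FlipAngle": 0,
    "EchoTime": 2,
    "RepetitionTime": 2,
    "InversionTime": 2
  },
  "ordinal_words": ["first", "second", "third", "fourth", "fifth", "sixth",
                    "seventh", "eighth", "ninth", "tenth"],
  "units": {
    "MagneticFieldStrength": "Tesla",
    "FlipAngle": "degree",
    "EchoTime": "ms",
    "RepetitionTime": "ms",
    "InversionTime": "ms"
  }
}
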