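{
  "notes": "SYNTHETIC placeholder literature values for iminodiacetate (IDA) and its uranyl complexes at 25 C, I = 0.1 M. The stepwise pKa values and the cumulative formation constants (referenced to free UO2^2+ and fully deprotonated IDA) stand in for critically selected stability constants, which the user should substitute from their own compilation. Nothing in the package depends on these particular numbers: every computation takes the chelator model as configuration input.",
  "chelator": {
    "pKa": [9.34, 2.61, 1.82],
    "species": [
      { "m": 1, "l": 1, "log10_beta": 8.3 },
      { "m": 1, "l": 2, "log10_beta": 15.1 },
      { "m": 2, "l": 2, "log10_beta": 18.0 }
    ]
  },
  "conditions": { "pH": 6, "T": 298, "ionic_strength": 0.1 }
}
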