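{
  "kBend": 10,
  "kTilt": 10,
  "epsRep": 10,
  "bRep": 20,
  "sRepCut": 1.35,
  "sRepHalf": 1.22,
  "epsAtt": 4.2,
  "rhoStar": 4.443,
  "attSharp": 6,
  "sRhoCut": 2.1,
  "sRhoHalf": 1.4,
  "alphaCv": 0.5,
  "rGa": 1.37,
  "rCc": 3.0
}
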