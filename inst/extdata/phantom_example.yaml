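# Example phantom configuration for `bonefuse.R phantom --config ...`.
# Omitted keys keep the package defaults (see ?phantomConfig).
phantom:
  ctShape: [128, 128, 128]
  ctSpacing: [2, 2, 2]
  spectShape: [32, 32, 32]
  spectSpacing: [8, 8, 8]
  seed: 42
  nVertebrae: 4
  ribPairs: 2
  pelvis: true
  bladderActivity: 20
  ctNoiseSd: 20
  psfFwhm: 10
  countBudget: 500000
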