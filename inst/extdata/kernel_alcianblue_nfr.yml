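stains:
- name: AlcianBlue
  azimuth: 35.0
  inclination: 76.0
- name: NuclearFastRed
  azimuth: 77.0
  inclination: 65.0
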