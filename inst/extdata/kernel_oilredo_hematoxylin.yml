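stains:
- name: OilRedO
  azimuth: 83.0
  inclination: 59.0
- name: Hematoxylin
  azimuth: 47.0
  inclination: 73.0
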