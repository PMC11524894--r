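classes:
- id: 0
  name: BACK
  group: background
  color: '#FFFFFF'
- id: 1
  name: TUMOR_LUAD
  group: tumor_region
  color: '#2CA02C'
- id: 2
  name: TUMOR_LUSC
  group: tumor_region
  color: '#D62728'
- id: 3
  name: TU_STROMA
  group: tumor_region
  color: '#FF9896'
- id: 4
  name: NECROSIS
  group: tumor_region
  color: '#1F3A93'
- id: 5
  name: MUCIN
  group: tumor_region
  color: '#17BECF'
mpp: 1.0
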