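classes:
- id: 0
  name: BACK
  group: background
  color: '#FFFFFF'
- id: 1
  name: TUMOR
  group: tumor_region
  color: '#D62728'
- id: 2
  name: TU_STROMA
  group: tumor_region
  color: '#FF9896'
- id: 3
  name: NECROSIS
  group: tumor_region
  color: '#1F3A93'
- id: 4
  name: MUCIN
  group: tumor_region
  color: '#17BECF'
- id: 5
  name: TLS
  group: benign
  color: '#FFD700'
- id: 6
  name: LUNG_BENIGN
  group: benign
  color: '#98DF8A'
- id: 7
  name: STROMA
  group: benign
  color: '#C49C94'
- id: 8
  name: BRONCH
  group: benign
  color: '#9467BD'
- id: 9
  name: BLOOD
  group: benign
  color: '#8C1717'
- id: 10
  name: GLAND_PERIBR
  group: benign
  color: '#E377C2'
- id: 11
  name: CARTIL
  group: benign
  color: '#7F7F7F'
mpp: 1.0
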