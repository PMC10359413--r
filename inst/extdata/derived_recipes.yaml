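- name: SFA sum
  type: sum
  select:
    is_dma: no
    max_db: 0.0
- name: MUFA sum
  type: sum
  select:
    is_dma: no
    min_db: 1.0
    max_db: 1.0
- name: PUFA sum
  type: sum
  select:
    is_dma: no
    min_db: 2.0
- name: n-3 PUFA sum
  type: sum
  select:
    series: n-3
    min_db: 2.0
- name: n-6 PUFA sum
  type: sum
  select:
    series: n-6
    min_db: 2.0
- name: DMA sum
  type: sum
  select:
    is_dma: yes
- name: C20-24 SFA sum
  type: sum
  select:
    is_dma: no
    max_db: 0.0
    min_carbons: 20.0
    max_carbons: 24.0
- name: n-3/n-6 ratio
  type: ratio
  numerator:
    series: n-3
    min_db: 2.0
  denominator:
    series: n-6
    min_db: 2.0
- name: n-6 product/precursor ratio
  type: ratio
  numerator:
    series: n-6
    min_db: 2.0
    min_carbons: 20.0
    max_carbons: 22.0
  denominator:
    labels: 18:2n-6
- name: n-3 product/precursor ratio
  type: ratio
  numerator:
    series: n-3
    min_db: 2.0
    min_carbons: 20.0
    max_carbons: 22.0
  denominator:
    labels: 18:3n-3
- name: double bond index
  type: index
  weight: double_bonds
- name: average chain length
  type: index
  weight: carbons
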