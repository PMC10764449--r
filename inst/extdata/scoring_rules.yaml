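version: '1.0'
cellularity:
  high: 3.0
  mid: 2.0
  low: 1.3
  inclusivity: score1=(mid,high]; score2=[low,mid]
alignment:
  high: 3.0
  mid: 2.1
  unity: 1.0
  dispersion_percent: 25.0
  inclusivity: score1=(mid,high]; score2 absorbs <=mid unless score3
col1:
  score1_areas:
  - 1.0
  - 2.0
  score2_areas:
  - 3.0
  - 4.0
  all_areas: 5.0
vascularity:
  levels:
  - plexus
  - scattered_or_aligned_le1_area
  - aligned_1_to_4_areas
  - few_aligned_as_healthy
metaplasia:
  all_areas: 5.0
  band1:
  - 2.0
  - 4.0
  band2: 1.0
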