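# Mapping from IAM (GCAM-style) land types to the four land system services.
# Types under `excluded` are treated as non-changing and dropped from demand.
cropland:
  - Corn
  - Fibre crop
  - Fodder grass
  - Fodder herb
  - Misc crop
  - Oil crop
  - Palm fruit
  - Rice
  - Root tuber
  - Sugar crop
  - Wheat
  - Biomass grass
  - Biomass tree
  - Other grain
  - Other arable land
forest:
  - Unmanaged forest
  - Protected unmanaged forest
  - Forest
grassland:
  - Unmanaged pasture
  - Protected grassland
  - Protected unmanaged pasture
  - Pasture
  - Grassland
shrubland:
  - Protected shrubland
  - Shrubland
excluded:
  - Tundra
  - Urban
  - Rocky
  - Snow or ice
  - Desert
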