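# Example run configuration: deciduous broadleaf forest with synthetic
# oak leaf spectra.  Omitted fields take the package defaults
# (solar zenith 30 deg, nadir view, direct-beam illumination; PAI grid
# 0.1-7; green proportions 0.5-0.98; MODIS-like band windows).
forest_type: DBF
seed: 1
spectra:
  leaf: oak          # built-in species profile, or a path to a CSV file
geometry:
  solar_zenith_deg: 30
  view_zenith_deg: 0
  relative_azimuth_deg: 0
  direct_fraction: 1.0
arrangement: blocks
vi:
  savi_L: 0.5
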