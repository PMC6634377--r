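# Example pipeline configuration: every analysis constant is a named key.
# Unspecified keys fall back to the package defaults (see default_config()).
seed: 42
views_per_sample: 60
minor_species_cutoff_pct: 3
cv:
  K: 10
  reps: 30
epochs:
  past: 1984
  current: 2016
exclude_gmus: []
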