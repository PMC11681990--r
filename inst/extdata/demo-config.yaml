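# Small demonstration configuration for the synthetic lateralization
# pipeline: 6 subjects per handedness group, 2 areas per hemisphere with one
# planted left-dominant area, completing in seconds.
seed: 42
simulate:
  n_per_group: 6
  n_parcels_per_hemi: 2
  vertices_per_parcel: 20
  baseline_mu: 0.5
  subject_sd: 0.5
  vertex_sd: 1.0
  contrast: STORY
  laterality_delta:
    P001: 2.0
analyze:
  trim: 0.2
  alpha: 0.05
  threshold_basis: full_map
  designs: [hemispheric, within_group, between_group]
  group_filters: [all]
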