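# Versioned rule tables and region vocabularies for MRI subtyping.
# All cut points live here, not in code, so the rule tables are auditable.
version: 1

regions:
  # Desikan cortical parcellation, 34 regions per hemisphere.
  cortical:
    - bankssts
    - caudalanteriorcingulate
    - caudalmiddlefrontal
    - cuneus
    - entorhinal
    - frontalpole
    - fusiform
    - inferiorparietal
    - inferiortemporal
    - insula
    - isthmuscingulate
    - lateraloccipital
    - lateralorbitofrontal
    - lingual
    - medialorbitofrontal
    - middletemporal
    - paracentral
    - parahippocampal
    - parsopercularis
    - parsorbitalis
    - parstriangularis
    - pericalcarine
    - postcentral
    - posteriorcingulate
    - precentral
    - precuneus
    - rostralanteriorcingulate
    - rostralmiddlefrontal
    - superiorfrontal
    - superiorparietal
    - superiortemporal
    - supramarginal
    - temporalpole
    - transversetemporal
  # Subcortical volumes carried by the schema; hippocampus and
  # lateral_ventricle are required by downstream derivations.
  subcortical:
    - hippocampus
    - lateral_ventricle
    - inferior_lateral_ventricle
    - amygdala
    - thalamus
    - caudate
    - putamen
    - pallidum
    - accumbens
    - ventraldc

# The three cortical regions whose averaged volume forms the denominator of
# the hippocampus-to-cortex (typicality) ratio. The middle frontal gyrus is
# represented by the sum of its two Desikan parcels.
typicality_regions:
  middle_frontal: [caudalmiddlefrontal, rostralmiddlefrontal]
  inferior_parietal: [inferiorparietal]
  superior_temporal: [superiortemporal]

# AD-signature cortical thickness composite regions.
signature_regions: [entorhinal, inferiortemporal, middletemporal, fusiform]

# Visual-rating abnormality cut points (score >= cut is abnormal).
cutpoints:
  mta:
    - {age_min: 45, age_max: 74, cut: 1.5}
    - {age_min: 75, age_max: 84, cut: 2.0}
    - {age_min: 85, age_max: 94, cut: 2.5}
  pa: 1.0
  gcaf: 1.0

# Age-adjusted severity bands on the BV/CSF index, descending thresholds:
# index >= no_atrophy -> "no_atrophy"; >= mild -> "mild"; >= moderate ->
# "moderate"; below -> "severe". A value exactly on a boundary falls in the
# less atrophic band.
# PLACEHOLDER VALUES, NON-CANONICAL: the published age-adjusted clinical
# cut-offs for the BV/CSF index are not restated in the source this package
# models; edit this table to use the published ones.
severity_bands:
  - {age_min: 45, age_max: 74, no_atrophy: 22.0, mild: 15.0, moderate: 9.0}
  - {age_min: 75, age_max: 84, no_atrophy: 18.0, mild: 12.0, moderate: 7.0}
  - {age_min: 85, age_max: 94, no_atrophy: 15.0, mild: 10.0, moderate: 6.0}
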