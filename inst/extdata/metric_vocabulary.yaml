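# Column vocabulary for the three raw metric tables and the bilateral pairing
# map used to reduce 133 raw columns to 74 variables. Bilateral labels appear
# once here; the raw tables carry "<label>_lh" and "<label>_rh" columns.
# Midline labels carry no suffix and pass through unchanged. Reduced columns
# are prefixed by modality (th_ / vol_ / fa_) so names stay unique after the
# three tables are joined.
thickness:
  bilateral:
    - bankssts
    - caudal_anterior_cingulate
    - caudal_middle_frontal
    - cuneus
    - entorhinal
    - frontal_pole
    - fusiform
    - inferior_parietal
    - inferior_temporal
    - insula
    - isthmus_cingulate
    - lateral_occipital
    - lateral_orbitofrontal
    - lingual
    - medial_orbitofrontal
    - middle_temporal
    - paracentral
    - parahippocampal
    - pars_opercularis
    - pars_orbitalis
    - pars_triangularis
    - pericalcarine
    - postcentral
    - posterior_cingulate
    - precentral
    - precuneus
    - rostral_anterior_cingulate
    - rostral_middle_frontal
    - superior_frontal
    - superior_parietal
    - superior_temporal
    - supramarginal
    - temporal_pole
    - transverse_temporal
  midline: []
volume:
  bilateral:
    - accumbens
    - amygdala
    - caudate
    - cerebellum_cortex
    - hippocampus
    - pallidum
    - putamen
    - thalamus
  midline:
    - cc_posterior
    - cc_middle
    - cc_central
    - cc_mid_anterior
    - cc_anterior
    - medulla
    - pons
    - superior_cerebellar_peduncle
    - midbrain
fa:
  bilateral:
    - anterior_thalamic_radiation
    - posterior_thalamic_radiation
    - cerebellar_wm
    - corticospinal_tract
    - inferior_cerebellar_peduncle
    - superior_cerebellar_peduncle
    - inferior_longitudinal_fasciculus
    - uncinate_fasciculus
    - superior_frontal
    - inferior_frontal
    - temporal
    - occipital
    - parietal
    - cingulum
    - inferior_fronto_occipital_fasciculus
    - superior_longitudinal_fasciculus
    - medial_lemniscus
  midline:
    - forceps_major
    - forceps_minor
    - cc_body
    - middle_cerebellar_peduncle
    - fornix
    - brainstem
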