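# The 15 regions of interest scored by the pipeline. Each ROI combines one
# grey-matter index (summed cortical thickness, or summed TIV-fraction volume
# for subcortical/infratentorial regions) with one white-matter index (summed
# FA). gm_members/wm_members reference reduced (bilaterally averaged) columns.
# wm_mode "separate" scales each FA member on its own instead of summing; the
# two resulting 0-1 indices are then added, so the composite still spans 0-2.
# Order below is the canonical ROI order used in all outputs.
- name: inferior_frontal
  gm_kind: thickness
  gm_members: [th_lateral_orbitofrontal, th_medial_orbitofrontal, th_pars_orbitalis,
               th_frontal_pole, th_rostral_anterior_cingulate]
  wm_mode: pooled
  wm_members: [fa_inferior_frontal]
- name: superior_frontal
  gm_kind: thickness
  gm_members: [th_superior_frontal, th_rostral_middle_frontal,
               th_caudal_middle_frontal, th_caudal_anterior_cingulate]
  wm_mode: pooled
  wm_members: [fa_superior_frontal]
- name: peri_sylvian
  gm_kind: thickness
  gm_members: [th_pars_opercularis, th_pars_triangularis, th_insula]
  wm_mode: pooled
  wm_members: [fa_uncinate_fasciculus]
- name: mesial_inferior_temporal
  gm_kind: thickness
  gm_members: [th_entorhinal, th_parahippocampal, th_fusiform, th_temporal_pole]
  wm_mode: pooled
  wm_members: [fa_inferior_longitudinal_fasciculus]
- name: superior_lateral_temporal
  gm_kind: thickness
  gm_members: [th_superior_temporal, th_middle_temporal, th_inferior_temporal,
               th_transverse_temporal, th_bankssts]
  wm_mode: pooled
  wm_members: [fa_temporal]
- name: parietal
  gm_kind: thickness
  gm_members: [th_inferior_parietal, th_superior_parietal, th_supramarginal,
               th_precuneus, th_posterior_cingulate, th_isthmus_cingulate]
  wm_mode: pooled
  wm_members: [fa_parietal]
- name: occipital
  gm_kind: thickness
  gm_members: [th_lateral_occipital, th_lingual, th_cuneus, th_pericalcarine]
  wm_mode: pooled
  wm_members: [fa_occipital]
- name: motor
  gm_kind: thickness
  gm_members: [th_precentral, th_paracentral]
  wm_mode: pooled
  wm_members: [fa_corticospinal_tract]
- name: commissural
  gm_kind: volume
  gm_members: [vol_cc_posterior, vol_cc_middle, vol_cc_central,
               vol_cc_mid_anterior, vol_cc_anterior]
  wm_mode: pooled
  wm_members: [fa_forceps_major, fa_forceps_minor, fa_cc_body]
- name: brainstem
  gm_kind: volume
  gm_members: [vol_medulla, vol_pons, vol_midbrain]
  wm_mode: pooled
  wm_members: [fa_brainstem]
- name: cerebellum
  gm_kind: volume
  gm_members: [vol_cerebellum_cortex, vol_superior_cerebellar_peduncle]
  wm_mode: pooled
  wm_members: [fa_inferior_cerebellar_peduncle, fa_middle_cerebellar_peduncle,
               fa_superior_cerebellar_peduncle, fa_cerebellar_wm]
- name: subcortical
  gm_kind: volume
  gm_members: [vol_thalamus, vol_caudate, vol_putamen, vol_pallidum, vol_accumbens]
  wm_mode: pooled
  wm_members: [fa_anterior_thalamic_radiation, fa_posterior_thalamic_radiation]
- name: limbic
  gm_kind: volume
  gm_members: [vol_amygdala, vol_hippocampus]
  wm_mode: pooled
  wm_members: [fa_fornix, fa_cingulum]
- name: long_association
  gm_kind: none
  gm_members: []
  wm_mode: separate
  wm_members: [fa_inferior_fronto_occipital_fasciculus,
               fa_superior_longitudinal_fasciculus]
- name: sensory
  gm_kind: thickness
  gm_members: [th_postcentral]
  wm_mode: pooled
  wm_members: [fa_medial_lemniscus]
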