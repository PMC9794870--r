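lh_caudalanteriorcingulate_area
lh_caudalanteriorcingulate_grayvol
lh_caudalanteriorcingulate_thickness
lh_caudalmiddlefrontal_area
lh_caudalmiddlefrontal_grayvol
lh_caudalmiddlefrontal_thickness
lh_cuneus_area
lh_cuneus_grayvol
lh_cuneus_thickness
lh_entorhinal_area
lh_entorhinal_grayvol
lh_entorhinal_thickness
lh_fusiform_area
lh_fusiform_grayvol
lh_fusiform_thickness
lh_inferiorparietal_area
lh_inferiorparietal_grayvol
lh_inferiorparietal_thickness
lh_inferiortemporal_area
lh_inferiortemporal_grayvol
lh_inferiortemporal_thickness
lh_isthmuscingulate_area
lh_isthmuscingulate_grayvol
lh_isthmuscingulate_thickness
lh_lateraloccipital_area
lh_lateraloccipital_grayvol
lh_lateraloccipital_thickness
lh_lateralorbitofrontal_area
lh_lateralorbitofrontal_grayvol
lh_lateralorbitofrontal_thickness
lh_lingual_area
lh_lingual_grayvol
lh_lingual_thickness
lh_medialorbitofrontal_area
lh_medialorbitofrontal_grayvol
lh_medialorbitofrontal_thickness
lh_middletemporal_area
lh_middletemporal_grayvol
lh_middletemporal_thickness
lh_parahippocampal_area
lh_parahippocampal_grayvol
lh_parahippocampal_thickness
lh_paracentral_area
lh_paracentral_grayvol
lh_paracentral_thickness
lh_parsopercularis_area
lh_parsopercularis_grayvol
lh_parsopercularis_thickness
lh_parsorbitalis_area
lh_parsorbitalis_grayvol
lh_parsorbitalis_thickness
lh_parstriangularis_area
lh_parstriangularis_grayvol
lh_parstriangularis_thickness
lh_pericalcarine_area
lh_pericalcarine_grayvol
lh_pericalcarine_thickness
lh_postcentral_area
lh_postcentral_grayvol
lh_postcentral_thickness
lh_posteriorcingulate_area
lh_posteriorcingulate_grayvol
lh_posteriorcingulate_thickness
lh_precentral_area
lh_precentral_grayvol
lh_precentral_thickness
lh_precuneus_area
lh_precuneus_grayvol
lh_precuneus_thickness
lh_rostralanteriorcingulate_area
lh_rostralanteriorcingulate_grayvol
lh_rostralanteriorcingulate_thickness
lh_rostralmiddlefrontal_area
lh_rostralmiddlefrontal_grayvol
lh_rostralmiddlefrontal_thickness
lh_superiorfrontal_area
lh_superiorfrontal_grayvol
lh_superiorfrontal_thickness
lh_superiorparietal_area
lh_superiorparietal_grayvol
lh_superiorparietal_thickness
lh_superiortemporal_area
lh_superiortemporal_grayvol
lh_superiortemporal_thickness
lh_supramarginal_area
lh_supramarginal_grayvol
lh_supramarginal_thickness
lh_transversetemporal_area
lh_transversetemporal_grayvol
lh_transversetemporal_thickness
lh_insula_area
lh_insula_grayvol
lh_insula_thickness
lh_frontalpole_area
lh_frontalpole_grayvol
lh_frontalpole_thickness
rh_caudalanteriorcingulate_area
rh_caudalanteriorcingulate_grayvol
rh_caudalanteriorcingulate_thickness
rh_caudalmiddlefrontal_area
rh_caudalmiddlefrontal_grayvol
rh_caudalmiddlefrontal_thickness
rh_cuneus_area
rh_cuneus_grayvol
rh_cuneus_thickness
rh_entorhinal_area
rh_entorhinal_grayvol
rh_entorhinal_thickness
rh_fusiform_area
rh_fusiform_grayvol
rh_fusiform_thickness
rh_inferiorparietal_area
rh_inferiorparietal_grayvol
rh_inferiorparietal_thickness
rh_inferiortemporal_area
rh_inferiortemporal_grayvol
rh_inferiortemporal_thickness
rh_isthmuscingulate_area
rh_isthmuscingulate_grayvol
rh_isthmuscingulate_thickness
rh_lateraloccipital_area
rh_lateraloccipital_grayvol
rh_lateraloccipital_thickness
rh_lateralorbitofrontal_area
rh_lateralorbitofrontal_grayvol
rh_lateralorbitofrontal_thickness
rh_lingual_area
rh_lingual_grayvol
rh_lingual_thickness
rh_medialorbitofrontal_area
rh_medialorbitofrontal_grayvol
rh_medialorbitofrontal_thickness
rh_middletemporal_area
rh_middletemporal_grayvol
rh_middletemporal_thickness
rh_parahippocampal_area
rh_parahippocampal_grayvol
rh_parahippocampal_thickness
rh_paracentral_area
rh_paracentral_grayvol
rh_paracentral_thickness
rh_parsopercularis_area
rh_parsopercularis_grayvol
rh_parsopercularis_thickness
rh_parsorbitalis_area
rh_parsorbitalis_grayvol
rh_parsorbitalis_thickness
rh_parstriangularis_area
rh_parstriangularis_grayvol
rh_parstriangularis_thickness
rh_pericalcarine_area
rh_pericalcarine_grayvol
rh_pericalcarine_thickness
rh_postcentral_area
rh_postcentral_grayvol
rh_postcentral_thickness
rh_posteriorcingulate_area
rh_posteriorcingulate_grayvol
rh_posteriorcingulate_thickness
rh_precentral_area
rh_precentral_grayvol
rh_precentral_thickness
rh_precuneus_area
rh_precuneus_grayvol
rh_precuneus_thickness
rh_rostralanteriorcingulate_area
rh_rostralanteriorcingulate_grayvol
rh_rostralanteriorcingulate_thickness
rh_rostralmiddlefrontal_area
rh_rostralmiddlefrontal_grayvol
rh_rostralmiddlefrontal_thickness
rh_superiorfrontal_area
rh_superiorfrontal_grayvol
rh_superiorfrontal_thickness
rh_superiorparietal_area
rh_superiorparietal_grayvol
rh_superiorparietal_thickness
rh_superiortemporal_area
rh_superiortemporal_grayvol
rh_superiortemporal_thickness
rh_supramarginal_area
rh_supramarginal_grayvol
rh_supramarginal_thickness
rh_transversetemporal_area
rh_transversetemporal_grayvol
rh_transversetemporal_thickness
rh_insula_area
rh_insula_grayvol
rh_insula_thickness
rh_frontalpole_area
rh_frontalpole_grayvol
rh_frontalpole_thickness
vol_Left-Lateral-Ventricle
vol_Right-Lateral-Ventricle
vol_Left-Inf-Lat-Vent
vol_Right-Inf-Lat-Vent
vol_3rd-Ventricle
vol_4th-Ventricle
vol_Left-Cerebellum-White-Matter
vol_Right-Cerebellum-White-Matter
vol_Left-Cerebellum-Cortex
vol_Right-Cerebellum-Cortex
vol_Left-Thalamus
vol_Right-Thalamus
vol_Left-Caudate
vol_Right-Caudate
vol_Left-Putamen
vol_Right-Putamen
vol_Left-Pallidum
vol_Right-Pallidum
vol_Left-Hippocampus
vol_Right-Hippocampus
vol_Left-Amygdala
vol_Right-Amygdala
vol_Left-Accumbens-area
vol_Right-Accumbens-area
vol_Left-VentralDC
vol_Right-VentralDC
vol_Brain-Stem
vol_CSF
vol_WM-hypointensities
vol_CC-Mid-Anterior
TotalBrainVol
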