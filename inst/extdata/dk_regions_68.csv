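region,hemisphere
lh_bankssts,L
lh_caudalanteriorcingulate,L
lh_caudalmiddlefrontal,L
lh_cuneus,L
lh_entorhinal,L
lh_fusiform,L
lh_inferiorparietal,L
lh_inferiortemporal,L
lh_isthmuscingulate,L
lh_lateraloccipital,L
lh_lateralorbitofrontal,L
lh_lingual,L
lh_medialorbitofrontal,L
lh_middletemporal,L
lh_parahippocampal,L
lh_paracentral,L
lh_parsopercularis,L
lh_parsorbitalis,L
lh_parstriangularis,L
lh_pericalcarine,L
lh_postcentral,L
lh_posteriorcingulate,L
lh_precentral,L
lh_precuneus,L
lh_rostralanteriorcingulate,L
lh_rostralmiddlefrontal,L
lh_superiorfrontal,L
lh_superiorparietal,L
lh_superiortemporal,L
lh_supramarginal,L
lh_frontalpole,L
lh_temporalpole,L
lh_transversetemporal,L
lh_insula,L
rh_bankssts,R
rh_caudalanteriorcingulate,R
rh_caudalmiddlefrontal,R
rh_cuneus,R
rh_entorhinal,R
rh_fusiform,R
rh_inferiorparietal,R
rh_inferiortemporal,R
rh_isthmuscingulate,R
rh_lateraloccipital,R
rh_lateralorbitofrontal,R
rh_lingual,R
rh_medialorbitofrontal,R
rh_middletemporal,R
rh_parahippocampal,R
rh_paracentral,R
rh_parsopercularis,R
rh_parsorbitalis,R
rh_parstriangularis,R
rh_pericalcarine,R
rh_postcentral,R
rh_posteriorcingulate,R
rh_precentral,R
rh_precuneus,R
rh_rostralanteriorcingulate,R
rh_rostralmiddlefrontal,R
rh_superiorfrontal,R
rh_superiorparietal,R
rh_superiortemporal,R
rh_supramarginal,R
rh_frontalpole,R
rh_temporalpole,R
rh_transversetemporal,R
rh_insula,R
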