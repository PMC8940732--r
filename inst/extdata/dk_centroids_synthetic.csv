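region,x,y,z,hemisphere
lh_bankssts,0.0872401856,-0.2243827701,0.9705882353,L
lh_caudalanteriorcingulate,-0.3683203117,0.1817285588,0.9117647059,L
lh_caudalmiddlefrontal,0.5012022388,0.1459029310,0.8529411765,L
lh_cuneus,-0.3155381384,-0.5194351219,0.7941176471,L
lh_entorhinal,-0.1318167401,0.6648059172,0.7352941176,L
lh_fusiform,0.5935972470,-0.4359241352,0.6764705882,L
lh_inferiorparietal,-0.7818560945,-0.0849303140,0.6176470588,L
lh_inferiortemporal,0.5474200269,0.6229346492,0.5588235294,L
lh_isthmuscingulate,0.0178949643,-0.8658404993,0.5000000000,L
lh_lateraloccipital,-0.6197428602,0.6490624847,0.4411764706,L
lh_lateralorbitofrontal,0.9219510469,-0.0617454089,0.3823529412,L
lh_lingual,-0.7388628740,-0.5911094427,0.3235294118,L
lh_medialorbitofrontal,0.1483112325,0.9528560091,0.2647058824,L
lh_middletemporal,0.5421787322,-0.8146500347,0.2058823529,L
lh_parahippocampal,-0.9603175958,0.2369890664,0.1470588235,L
lh_paracentral,0.8743116140,0.4772774188,0.0882352941,L
lh_parsopercularis,-0.3234159112,-0.9457997127,0.0294117647,L
lh_parsorbitalis,-0.4004016986,0.9158675820,-0.0294117647,L
lh_parstriangularis,0.9107328807,-0.4034602247,-0.0882352941,L
lh_pericalcarine,-0.9374717363,-0.3154686135,-0.1470588235,L
lh_postcentral,0.4730659074,0.8566335880,-0.2058823529,L
lh_posteriorcingulate,0.2264774880,-0.9373573189,-0.2647058824,L
lh_precentral,-0.7851451576,0.5280869259,-0.3235294118,L
lh_precuneus,0.9137051909,0.1376555574,-0.3823529412,L
lh_rostralanteriorcingulate,-0.5640369564,-0.6980154967,-0.4411764706,L
lh_rostralmiddlefrontal,-0.0536543302,0.8643617373,-0.5000000000,L
lh_superiorfrontal,0.5969836096,-0.5756099659,-0.5588235294,L
lh_superiorparietal,-0.7861988619,0.0200863186,-0.6176470588,L
lh_superiortemporal,0.5555783990,0.4834461560,-0.6764705882,L
lh_supramarginal,-0.0764769171,-0.6734195139,-0.7352941176,L
lh_frontalpole,-0.3573479940,0.4916091677,-0.7941176471,L
lh_temporalpole,0.5115374593,-0.1040229650,-0.8529411765,L
lh_transversetemporal,-0.3520583122,-0.2115184765,-0.9117647059,L
lh_insula,0.0684161365,0.2308196477,-0.9705882353,L
rh_bankssts,-0.0872401856,-0.2243827701,0.9705882353,R
rh_caudalanteriorcingulate,0.3683203117,0.1817285588,0.9117647059,R
rh_caudalmiddlefrontal,-0.5012022388,0.1459029310,0.8529411765,R
rh_cuneus,0.3155381384,-0.5194351219,0.7941176471,R
rh_entorhinal,0.1318167401,0.6648059172,0.7352941176,R
rh_fusiform,-0.5935972470,-0.4359241352,0.6764705882,R
rh_inferiorparietal,0.7818560945,-0.0849303140,0.6176470588,R
rh_inferiortemporal,-0.5474200269,0.6229346492,0.5588235294,R
rh_isthmuscingulate,-0.0178949643,-0.8658404993,0.5000000000,R
rh_lateraloccipital,0.6197428602,0.6490624847,0.4411764706,R
rh_lateralorbitofrontal,-0.9219510469,-0.0617454089,0.3823529412,R
rh_lingual,0.7388628740,-0.5911094427,0.3235294118,R
rh_medialorbitofrontal,-0.1483112325,0.9528560091,0.2647058824,R
rh_middletemporal,-0.5421787322,-0.8146500347,0.2058823529,R
rh_parahippocampal,0.9603175958,0.2369890664,0.1470588235,R
rh_paracentral,-0.8743116140,0.4772774188,0.0882352941,R
rh_parsopercularis,0.3234159112,-0.9457997127,0.0294117647,R
rh_parsorbitalis,0.4004016986,0.9158675820,-0.0294117647,R
rh_parstriangularis,-0.9107328807,-0.4034602247,-0.0882352941,R
rh_pericalcarine,0.9374717363,-0.3154686135,-0.1470588235,R
rh_postcentral,-0.4730659074,0.8566335880,-0.2058823529,R
rh_posteriorcingulate,-0.2264774880,-0.9373573189,-0.2647058824,R
rh_precentral,0.7851451576,0.5280869259,-0.3235294118,R
rh_precuneus,-0.9137051909,0.1376555574,-0.3823529412,R
rh_rostralanteriorcingulate,0.5640369564,-0.6980154967,-0.4411764706,R
rh_rostralmiddlefrontal,0.0536543302,0.8643617373,-0.5000000000,R
rh_superiorfrontal,-0.5969836096,-0.5756099659,-0.5588235294,R
rh_superiorparietal,0.7861988619,0.0200863186,-0.6176470588,R
rh_superiortemporal,-0.5555783990,0.4834461560,-0.6764705882,R
rh_supramarginal,0.0764769171,-0.6734195139,-0.7352941176,R
rh_frontalpole,0.3573479940,0.4916091677,-0.7941176471,R
rh_temporalpole,-0.5115374593,-0.1040229650,-0.8529411765,R
rh_transversetemporal,0.3520583122,-0.2115184765,-0.9117647059,R
rh_insula,-0.0684161365,0.2308196477,-0.9705882353,R
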