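(((Hyla_versicolor,(Pseudacris_crucifer,Pseudacris_triseriata)),((Rana_catesbeiana,(Rana_clamitans,(Rana_pipiens,Rana_palustris))),Rana_sylvatica)),(((Ambystoma_laterale,(Ambystoma_maculatum,Ambystoma_tigrinum)),Hemidactylium_scutatum),Notophthalmus_viridescens));
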