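"id","label","n_states","ordered","organ_block","state_labels"
"flw_sex","Flower sex",2,FALSE,"flower","bisexual|unisexual"
"per_presence","Perianth presence",2,FALSE,"perianth","absent|present"
"per_phyllotaxis","Perianth phyllotaxis",3,FALSE,"perianth","spiral|whorled|irregular"
"per_merism","Perianth merism",5,TRUE,"perianth","dimerous|trimerous|tetramerous|pentamerous|polymerous"
"per_whorls","Number of perianth whorls/series",4,TRUE,"perianth","one|two|three|more than three"
"per_differentiation","Perianth differentiation",3,FALSE,"perianth","undifferentiated|sepals and petals|graded"
"per_fusion","Perianth fusion",2,FALSE,"perianth","free|fused"
"per_symmetry","Floral (perianth) symmetry",3,FALSE,"perianth","actinomorphic|zygomorphic|asymmetric"
"per_petaloidy","Petaloid organs present",2,FALSE,"perianth","no|yes"
"and_stamen_number","Stamen number class",5,TRUE,"androecium","one|2-5|6-10|11-20|more than 20"
"and_phyllotaxis","Androecium phyllotaxis",3,FALSE,"androecium","spiral|whorled|irregular"
"and_merism","Androecium merism class",4,TRUE,"androecium","dimerous|trimerous|tetra-pentamerous|polymerous"
"and_whorls","Number of androecium whorls",4,TRUE,"androecium","one|two|three|more than three"
"and_stamen_fusion","Fusion of stamens",2,FALSE,"androecium","free|fused"
"and_per_fusion","Stamen-perianth fusion",2,FALSE,"androecium","free|fused"
"and_anther_attachment","Anther attachment",2,FALSE,"androecium","basifixed|dorsifixed"
"and_anther_dehiscence","Anther dehiscence",3,FALSE,"androecium","longitudinal slits|valvate|poricidal"
"and_anther_orientation","Anther orientation",2,FALSE,"androecium","introrse|extrorse"
"and_staminodes","Staminodes present",2,FALSE,"androecium","no|yes"
"and_filament","Filament differentiation",2,FALSE,"androecium","undifferentiated|distinct filament"
"gyn_carpel_number","Carpel number class",3,TRUE,"gynoecium","one|2-5|more than 5"
"gyn_fusion","Carpel fusion",3,FALSE,"gynoecium","apocarpous|partly syncarpous|fully syncarpous"
"gyn_ovary_position","Ovary position",3,TRUE,"gynoecium","superior|half-inferior|inferior"
"gyn_style","Style differentiation",2,FALSE,"gynoecium","undifferentiated|differentiated"
"gyn_phyllotaxis","Gynoecium phyllotaxis",2,FALSE,"gynoecium","spiral|whorled"
"gyn_ovule_number","Ovules per carpel",2,FALSE,"gynoecium","one|several"
"gyn_sealing","Carpel sealing",2,FALSE,"gynoecium","by secretion|postgenital fusion"
"gyn_stigma","Stigma extent",2,FALSE,"gynoecium","restricted|extended"
"pol_apertures","Pollen aperture number",2,FALSE,"pollen","up to one|two or more"
"pol_tectum","Pollen tectum",2,FALSE,"pollen","continuous/microperforate|perforate/reticulate"
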