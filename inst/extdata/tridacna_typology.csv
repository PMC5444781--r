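class_id,level3,level2,level1,depth_stratum,density_mean,density_sd
fringing,Fringing reef of continental island,Shallow reefs,Reef,shallow,256,272
intermediate,Intermediate reef of continental island,Shallow reefs,Reef,shallow,200,84
outer_barrier,Outer barrier reef of continental island,Shallow reefs,Reef,shallow,329,269
oceanic_patch,Oceanic patch reef of continental island,Shallow reefs,Reef,shallow,104,42
oceanic_island,Oceanic island,Shallow reefs,Reef,shallow,109,93
atoll_bank,Atoll/Bank reef,Shallow reefs,Reef,shallow,234,0
shallow_reefs,,Shallow reefs,Reef,shallow,224,193
reef,,,Reef,all,224,193
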