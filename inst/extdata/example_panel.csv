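channel,marker,use_for_clustering
Ch001,CD45,TRUE
Ch002,CD3,TRUE
Ch003,CD19,TRUE
Ch004,CD4,TRUE
Ch005,CD8,TRUE
Ch006,KLRG1,TRUE
Ch007,KLRF1,TRUE
Ch008,AICL,TRUE
Ch009,PD1,TRUE
Ch010,CK18,FALSE
Ch011,aSMA,FALSE
Ch012,DNA1,FALSE
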