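channel,CD45,CD3,CD19,CD4,CD8,KLRG1,KLRF1,AICL,PD1,CK18,aSMA,DNA1
CD45,1,0.03,0,0,0,0,0,0,0,0,0,0
CD3,0,1,0.03,0.05,0,0,0,0,0,0,0,0
CD19,0,0,1,0.03,0,0,0,0,0,0,0,0
CD4,0,0,0,1,0.03,0,0,0,0,0,0,0
CD8,0,0,0,0,1,0.03,0,0,0,0,0,0
KLRG1,0,0,0,0,0,1,0.03,0,0,0,0,0
KLRF1,0,0,0,0,0,0,1,0.03,0,0,0,0
AICL,0,0,0,0,0,0,0,1,0.03,0,0,0
PD1,0,0,0,0,0,0,0,0,1,0.03,0,0
CK18,0,0,0,0,0,0,0,0,0,1,0.03,0
aSMA,0,0,0,0,0,0,0,0,0,0,1,0.03
DNA1,0,0,0,0,0,0,0,0,0,0,0,1
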