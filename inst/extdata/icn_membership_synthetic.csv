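roi_label,icn_name
dDMN_1,dDMN
dDMN_2,dDMN
dDMN_3,dDMN
dDMN_4,dDMN
dDMN_5,dDMN
dDMN_6,dDMN
vDMN_1,vDMN
vDMN_2,vDMN
vDMN_3,vDMN
vDMN_4,vDMN
vDMN_5,vDMN
vDMN_6,vDMN
Prec_1,Prec
Prec_2,Prec
Prec_3,Prec
Prec_4,Prec
Prec_5,Prec
Prec_6,Prec
lECN_1,lECN
lECN_2,lECN
lECN_3,lECN
lECN_4,lECN
lECN_5,lECN
lECN_6,lECN
rECN_1,rECN
rECN_2,rECN
rECN_3,rECN
rECN_4,rECN
rECN_5,rECN
rECN_6,rECN
aSal_1,aSal
aSal_2,aSal
aSal_3,aSal
aSal_4,aSal
aSal_5,aSal
aSal_6,aSal
pSal_1,pSal
pSal_2,pSal
pSal_3,pSal
pSal_4,pSal
pSal_5,pSal
pSal_6,pSal
SM_1,SM
SM_2,SM
SM_3,SM
SM_4,SM
SM_5,SM
SM_6,SM
VS_1,VS
VS_2,VS
VS_3,VS
VS_4,VS
VS_5,VS
VS_6,VS
hVis_1,hVis
hVis_2,hVis
hVis_3,hVis
hVis_4,hVis
hVis_5,hVis
hVis_6,hVis
pVis_1,pVis
pVis_2,pVis
pVis_3,pVis
pVis_4,pVis
pVis_5,pVis
pVis_6,pVis
Lang_1,Lang
Lang_2,Lang
Lang_3,Lang
Lang_4,Lang
Lang_5,Lang
Lang_6,Lang
Aud_1,Aud
Aud_2,Aud
Aud_3,Aud
Aud_4,Aud
Aud_5,Aud
Aud_6,Aud
BG_1,BG
BG_2,BG
BG_3,BG
BG_4,BG
BG_5,BG
BG_6,BG
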