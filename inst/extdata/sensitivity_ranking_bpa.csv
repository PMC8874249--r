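output,rank,parameter
serum_BPA,1,KM_liv_BPA_in_vitro
serum_BPA,2,MPY
serum_BPA,3,Vmax_liv_BPA_in_vitro
serum_BPA,4,VliC
serum_BPA,5,KEMAX
serum_BPA,6,FB_BPA
serum_BPA,7,FracDOSEHep
serum_BPA,8,VspdC
serum_BPA,9,BELLYPERM
serum_BPA,10,Pstb
serum_BPAG,1,FB_BPAG
serum_BPAG,2,FracDOSEHep
serum_BPAG,3,VspdC
serum_BPAG,4,Vmax_gut_BPAS_in_vitro
serum_BPAG,5,Pstb
serum_BPAG,6,VguC
serum_BPAG,7,VliC
serum_BPAG,8,VBldC
serum_BPAG,9,BELLYPERM
serum_BPAG,10,KEMAX
serum_BPAS,1,FB_BPAS
serum_BPAS,2,Vmax_gut_BPAS_in_vitro
serum_BPAS,3,KM_gut_BPAS_in_vitro
serum_BPAS,4,BELLYPERM
serum_BPAS,5,MPY
serum_BPAS,6,KM_liv_BPA_in_vitro
serum_BPAS,7,VguC
serum_BPAS,8,FracDOSEHep
serum_BPAS,9,Vmax_liv_BPA_in_vitro
serum_BPAS,10,KEMAX
CVli,1,KM_liv_BPA_in_vitro
CVli,2,MPY
CVli,3,KEMAX
CVli,4,Vmax_liv_BPA_in_vitro
CVli,5,VliC
CVli,6,BELLYPERM
CVli,7,FracDOSEHep
CVli,8,Pgub
CVli,9,VspdC
CVli,10,Pstb
CVki,1,KM_liv_BPA_in_vitro
CVki,2,K1_BPA_REMOVED_PLASMA
CVki,3,Vmax_liv_BPA_in_vitro
CVki,4,MPY
CVki,5,Pkib
CVki,6,VliC
CVki,7,VspdC
CVki,8,FracDOSEHep
CVki,9,Pstb
CVki,10,QCC
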