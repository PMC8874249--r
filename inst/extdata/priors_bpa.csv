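parameter,unit,distribution,mean,sd,lower,upper,scope
BW,kg,lognormal,4.36,0.313,3.747,4.973,global
VliC,L/kg,normal,0.0350,0.00758,0.021,0.0490,individual
VstC,L/kg,normal,0.0210,0.00069,0.021,0.0235,global
VguC,L/kg,normal,0.0150,0.00234,0.008,0.0220,global
VkiC,L/kg,normal,0.0058,0.00148,0.002,0.0100,global
VlymphC,L/kg,normal,0.0036,0.0007,0.0022,0.0050,global
VfaC,L/kg,normal,0.1950,0.0400,0.1200,0.2800,global
VspdC,L/kg,normal,0.6050,0.1000,0.4500,0.7500,global
VrpdC,L/kg,normal,0.0284,0.0020,0.0120,0.0450,individual
VBldC,L/kg,normal,0.0600,0.0080,0.0410,0.0790,individual
QCC,L/h/kg^0.75,normal,12.0,2,11.1,12.98,individual
QhepartC,unitless,normal,0.0690,0.0060,0.0500,0.0900,global
QstC,unitless,normal,0.0110,0.0009,0.0040,0.0160,individual
QguC,unitless,normal,0.1700,0.0130,0.1100,0.2300,individual
QkiC,unitless,normal,0.2000,0.05,0.1000,0.2980,individual
QfaC,unitless,normal,0.0500,0.0050,0.0300,0.0699,global
QspdC,unitless,normal,0.2870,0.0221,0.2100,0.3600,global
QrpdC,unitless,normal,0.2100,0.0168,0.1600,0.2700,global
FracDOSEHep,unitless,uniform,NA,NA,0.715,0.914,individual
FracDOSELymph,unitless,uniform,NA,NA,0.021,0.079,individual
FB_BPA,unitless,uniform,NA,NA,0.023,0.962,global
FB_BPAG,unitless,uniform,NA,NA,0.707,0.982,global
FB_BPAS,unitless,uniform,NA,NA,0.707,0.982,global
MPY,mg/g,normal,34,7,14.6,53.7,individual
MPYgu,mg/g,normal,3.9,0.8,2.3,5.5,global
BELLYPERM,1/h,uniform,NA,NA,0.1,10,global
GIPERM,1/h,uniform,NA,NA,0.5,25,global
BELLYPERMLymph,1/h,uniform,NA,NA,0.84,2.5,global
GIPERMLymph,1/h,uniform,NA,NA,0.55,1.6,global
KEMAX,1/h,uniform,NA,NA,0.1,25,global
KEMIN,1/h,uniform,NA,NA,0.0025,0.0075,global
K1_BPA_GUT,1/h,uniform,NA,NA,0.55,1.6,global
K1_BPAG_GUT,1/h,uniform,NA,NA,0.01,20,global
K1_BPAS_GUT,1/h,uniform,NA,NA,0.55,1.6,global
K1_BPA_LIVER,1/h,uniform,NA,NA,0.55,1.6,global
K1_BPAG_LIVER,1/h,uniform,NA,NA,0.005,0.015,global
K1_BPAS_LIVER,1/h,uniform,NA,NA,0.005,0.015,global
K1_BPA_Urine,1/h,uniform,NA,NA,0.0005,0.0015,global
K1_BPAG_Urine,1/h,uniform,NA,NA,0.0005,0.0015,global
K1_BPAS_Urine,1/h,uniform,NA,NA,0.00005,0.00015,global
K1_BPA_REMOVED_PLASMA,1/h,uniform,NA,NA,2.41,97.48,global
K1_BPAG_REMOVED_PLASMA,1/h,uniform,NA,NA,13.22,146.58,global
K1_BPAS_REMOVED_PLASMA,1/h,uniform,NA,NA,2.41,97.48,global
K1Lymph,1/h,uniform,NA,NA,0.262,0.738,global
Lymphlag,h,uniform,NA,NA,0.28,1.47,individual
Vmax_liv_BPA_in_vitro,pmol/min/mg,normal,4494,900,1183,7839,global
KM_liv_BPA_in_vitro,mg/L,normal,1.31,0.20,0.154,2.44,global
Vmax_liv_BPAS_in_vitro,pmol/min/mg,normal,73,40,16.50,132.18,global
KM_liv_BPAS_in_vitro,mg/L,normal,4.00,0.6,1.63,6.37,global
Vmax_gut_BPAG_in_vitro,pmol/min/mg,normal,610,100,262,957,global
KM_gut_BPAG_in_vitro,mg/L,normal,22.98,4,9.8,35.10,global
Vmax_gut_BPAS_in_vitro,pmol/min/mg,normal,73,10,16.5,132.18,global
KM_gut_BPAS_in_vitro,mg/L,normal,4.00,0.6,1.63,6.37,global
Pbab,unitless,uniform,NA,NA,0.36,1.1,global
Plib,unitless,uniform,NA,NA,0.36,1.1,global
Pkib,unitless,uniform,NA,NA,1.35,14.67,global
Pfab,unitless,uniform,NA,NA,1.35,14.67,global
Pgub,unitless,uniform,NA,NA,1.35,14.67,global
Pstb,unitless,uniform,NA,NA,1.35,14.67,global
Prpdb,unitless,uniform,NA,NA,1.4,4.2,global
Pspdb,unitless,uniform,NA,NA,1.4,4.2,global
PbaG,unitless,uniform,NA,NA,0.7,2.1,global
PliG,unitless,uniform,NA,NA,1.59,22.49,global
PkiG,unitless,uniform,NA,NA,1.59,22.49,global
PfaG,unitless,uniform,NA,NA,1.2,3.60,global
PguG,unitless,uniform,NA,NA,1.59,22.49,global
PstG,unitless,uniform,NA,NA,1.70,5.3,global
PrpdG,unitless,uniform,NA,NA,2.1,6.4,global
PspdG,unitless,uniform,NA,NA,1,3,global
PbaS,unitless,uniform,NA,NA,0.7,2.1,global
PliS,unitless,uniform,NA,NA,1.59,22.49,global
PkiS,unitless,uniform,NA,NA,1.59,22.49,global
PfaS,unitless,uniform,NA,NA,1.3,3.9,global
PguS,unitless,uniform,NA,NA,1.59,22.49,global
PstS,unitless,uniform,NA,NA,1.9,5.7,global
PrpdS,unitless,uniform,NA,NA,2.3,6.8,global
PspdS,unitless,uniform,NA,NA,1,3.1,global
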