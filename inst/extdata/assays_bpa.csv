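assay,conc_um,log10_conc_um,response,response_type
ATG_PXR_TRANS_up,0.01,-2.000,-0.050,log2_fold_induction
ATG_PXR_TRANS_up,0.03,-1.523,0.257,log2_fold_induction
ATG_PXR_TRANS_up,0.09,-1.046,0.056,log2_fold_induction
ATG_PXR_TRANS_up,0.3,-0.523,0.277,log2_fold_induction
ATG_PXR_TRANS_up,0.8,-0.097,1.689,log2_fold_induction
ATG_PXR_TRANS_up,2,0.301,2.711,log2_fold_induction
ATG_PXR_TRANS_up,7,0.845,2.740,log2_fold_induction
ATG_PXR_TRANS_up,20,1.301,2.547,log2_fold_induction
ATG_PXR_TRANS_up,70,1.845,2.340,log2_fold_induction
ATG_ERE_CIS_up,0.01,-2.000,-0.122,log2_fold_induction
ATG_ERE_CIS_up,0.03,-1.523,0.239,log2_fold_induction
ATG_ERE_CIS_up,0.09,-1.046,1.144,log2_fold_induction
ATG_ERE_CIS_up,0.3,-0.523,2.046,log2_fold_induction
ATG_ERE_CIS_up,0.8,-0.097,2.442,log2_fold_induction
ATG_ERE_CIS_up,2,0.301,2.717,log2_fold_induction
ATG_ERE_CIS_up,7,0.845,2.368,log2_fold_induction
ATG_ERE_CIS_up,20,1.301,2.053,log2_fold_induction
ATG_ERE_CIS_up,70,1.845,2.427,log2_fold_induction
OT_ER_ERaERb_0480,0.003,-2.523,-6.989,percentage_activity
OT_ER_ERaERb_0480,0.003,-2.523,-4.593,percentage_activity
OT_ER_ERaERb_0480,0.003,-2.523,-4.548,percentage_activity
OT_ER_ERaERb_0480,0.01,-2.000,2.330,percentage_activity
OT_ER_ERaERb_0480,0.01,-2.000,-0.599,percentage_activity
OT_ER_ERaERb_0480,0.01,-2.000,3.617,percentage_activity
OT_ER_ERaERb_0480,0.03,-1.523,-5.303,percentage_activity
OT_ER_ERaERb_0480,0.03,-1.523,-5.480,percentage_activity
OT_ER_ERaERb_0480,0.03,-1.523,-0.333,percentage_activity
OT_ER_ERaERb_0480,0.1,-1.000,-0.954,percentage_activity
OT_ER_ERaERb_0480,0.1,-1.000,-1.176,percentage_activity
OT_ER_ERaERb_0480,0.1,-1.000,2.019,percentage_activity
OT_ER_ERaERb_0480,0.3,-0.523,26.914,percentage_activity
OT_ER_ERaERb_0480,0.3,-0.523,30.286,percentage_activity
OT_ER_ERaERb_0480,0.3,-0.523,24.074,percentage_activity
OT_ER_ERaERb_0480,1,0.000,72.620,percentage_activity
OT_ER_ERaERb_0480,1,0.000,78.744,percentage_activity
OT_ER_ERaERb_0480,1,0.000,60.373,percentage_activity
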