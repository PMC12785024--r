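species,band_id,label,literature_center_cm1,search_tol_cm1,track_tol_cm1,sigma_cm1,gamma_cm1,role
ALP,ALP_3398,Amide A N-H stretch,3398,25,7.5,12,8,band
ALP,ALP_2944,C-H stretch (alkyl),2944,25,7.5,5,3,band
ALP,ALP_2889,C-H stretch (alkyl),2889,25,7.5,5,3,band
ALP,ALP_1708,Amide I (beta-turn),1708,25,7.5,3.5,3,band
ALP,ALP_1624,Amide I (beta-sheet),1624,25,7.5,3.5,3,band
ALP,ALP_1551,Amide II,1551,25,7.5,3.5,3,band
ALP,ALP_1531,Amide II,1531,25,7.5,3.5,3,band
ALP,ALP_1459,CH2 scissoring,1459,25,7.5,3.5,3,band
ALP,ALP_1418,COO- symmetric stretch,1418,25,7.5,3.5,3,band
ALP,ALP_1334,CH2 wagging,1334,25,7.5,3.5,3,band
ALP,ALP_1215,Amide III,1215,25,7.5,3.5,3,band
ALP,ALP_1045,carbohydrate C-O (context),1045,25,7.5,3.5,3,context
ALP,ALP_925,skeletal/carbohydrate (context),925,25,7.5,3.5,3,context
PNPP,PNPP_1591,aromatic C=C,1591,25,7.5,3.5,3,band
PNPP,PNPP_1508,NO2 asymmetric stretch,1508,25,7.5,3.5,3,band
PNPP,PNPP_1496,NO2 symmetric stretch,1496,25,7.5,3.5,3,band
PNP,PNP_1595,aromatic C=C,1595,25,7.5,3.5,3,band
PNP,PNP_1390,NO2 stretch,1390,25,7.5,3.5,3,band
PNP,PNP_1320,NO2 stretch,1320,25,7.5,3.5,3,band
Pi,Pi_1077,P-O stretch (product marker),1077,25,7.5,3.5,3,band
Pi,Pi_847,P-O stretch (broad),847,25,7.5,3.5,8,band
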