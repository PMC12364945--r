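"diarrhea","abdominal_pain","abdominal_distension","bloody_purulent_stool","tenesmus","perianal_abscess","anal_fissure","anal_fistula","nutritional_deficiency","weight_loss","anemia","skin_lesions","oral_mucosal_lesions","ocular_lesions","fatigue","anxiety","depression","disturbed_sleep","active_stage","years_since_diagnosis","treatment_surgery","treatment_both","treatment_otherwise"
1,2,2,2,3,1,1,1,5,2,4,1,1,1,5,5,5,5,1,7.51867850246654,0,0,0
4,2,3,1,1,1,1,1,1,1,2,3,4,4,2,1,1,2,1,2.20588077530771,0,1,0
2,2,4,3,4,1,3,5,5,5,3,1,1,1,2,1,1,2,0,0.778946755162125,0,0,0
2,4,2,1,2,1,1,1,2,2,2,1,1,1,2,1,1,2,1,1.90372716783065,1,0,0
1,2,4,5,5,5,4,4,2,2,4,1,1,1,2,3,1,4,1,2.80938354414966,0,0,0
3,2,1,3,3,2,1,1,2,1,2,2,1,1,1,2,5,1,1,4.13411699670582,0,0,0
1,2,1,1,1,1,1,1,3,2,3,2,2,1,2,1,1,4,1,0.509131235346917,0,0,0
2,1,2,1,2,1,1,1,1,1,1,1,2,1,2,1,1,2,0,4.56392156869694,0,0,0
2,1,1,1,1,1,1,1,1,1,1,1,1,1,2,1,1,1,0,1.08542164208338,0,0,0
3,5,4,5,3,3,1,3,4,2,3,1,2,1,4,2,1,2,0,1.60778469085968,0,0,0
2,4,3,4,3,2,1,1,2,4,3,1,1,3,3,2,2,5,0,2.6074144983475,0,0,1
1,3,3,3,4,1,1,2,1,1,3,1,2,3,4,1,1,2,0,4.9488074003971,0,1,0
2,3,1,1,2,1,1,1,2,1,1,1,1,1,4,4,2,4,1,1.83697135236806,0,0,0
3,1,1,1,2,1,1,1,1,5,2,1,1,1,2,4,1,3,1,4.59510609171314,0,0,0
4,3,3,4,3,1,1,1,2,5,5,1,1,3,2,4,4,4,1,4.64079060918649,0,0,0
1,1,1,1,1,1,1,1,3,1,2,1,2,1,5,2,2,1,1,3.10296980692632,0,0,0
3,3,1,2,1,1,1,1,1,2,2,1,1,1,3,3,2,3,0,3.82272154425522,0,1,0
2,1,1,1,1,1,1,1,1,1,1,1,1,1,1,2,1,2,0,1.17834547225373,0,0,0
4,4,3,1,2,1,1,1,2,3,1,1,3,1,3,5,1,5,1,1.38301703744458,0,0,1
3,4,2,2,3,1,1,3,5,3,2,2,1,1,3,5,4,3,1,2.94902458938313,0,1,0
3,5,2,4,5,1,2,1,3,5,4,1,1,1,2,1,4,2,1,7.72084815587797,0,1,0
1,5,4,2,4,1,1,1,1,1,1,1,1,1,3,4,3,4,1,2.14406446444104,0,0,1
5,5,1,1,2,1,1,1,1,1,1,5,1,5,4,5,1,4,1,9.66092949125789,0,0,1
3,2,3,2,5,1,1,2,3,4,1,1,1,1,1,2,1,3,1,4.15993836848644,0,1,0
5,2,5,4,5,4,2,4,5,5,5,1,1,1,3,2,1,2,1,3.65175233139561,0,0,1
1,2,3,3,3,3,1,1,1,1,2,1,1,2,4,1,2,2,1,3.96320841482091,0,0,0
2,4,3,4,3,1,1,2,3,2,5,1,1,1,3,1,2,2,1,7.55480084091833,0,0,0
2,3,1,1,1,1,1,1,1,1,1,3,3,2,2,1,2,3,1,1.3912977878414,0,1,0
1,2,2,1,1,1,1,1,1,4,2,1,1,1,5,5,3,3,1,2.30860352174931,0,0,0
2,4,3,4,3,1,1,1,3,1,1,1,1,1,5,2,4,5,1,3.29633206492274,0,1,0
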