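sample,solvent,ic50_ache,sd_ache,ic50_cos7,sd_cos7,ratio_printed
Berberis bealei,MeOH,34.10,4.89,35.37,4.21,1.0
Berberis bealei,CH2Cl2,9.99,1.18,13.36,1.76,1.3
Berberis bealei,H2O,87.77,4.11,270.0,13.5,3.1
Coptis chinensis,MeOH,0.031,0.002,3.72,0.74,120
Coptis chinensis,CH2Cl2,8.13,0.90,39.57,4.87,4.9
Coptis chinensis,H2O,2.5,0.61,118.3,7.4,47
Phellodendron chinense,MeOH,8.03,0.98,85.52,11.90,10
Phellodendron chinense,CH2Cl2,6.34,1.37,71.33,6.87,11
Phellodendron chinense,H2O,84.83,1.84,282.9,15.3,3.3
Berberine,,1.48,0.07,,,
Coptisine,,1.27,0.06,,,
Palmatine,,5.21,0.48,,,
Physostigmine,,2.24,0.27,,,
Galantamine,,4.33,0.21,,,
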