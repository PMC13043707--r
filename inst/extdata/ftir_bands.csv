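name,lo_cm1,hi_cm1,reference_set
ch2_rock,710,740,TRUE
amide_III,1200,1300,TRUE
amide_II,1480,1585,TRUE
amide_I,1590,1720,TRUE
carbonyl_1821,1790,1855,TRUE
carbonyl_1929,1895,1960,TRUE
water_combination,2070,2190,TRUE
thiol,2450,2530,TRUE
ch_stretch,2840,2990,TRUE
ch_unsaturated,2995,3035,TRUE
strOH,3200,3450,TRUE
syOH,3450,3550,TRUE
asyOH,3550,3700,TRUE
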