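group,name,center_cm1,fwhm_cm1,fraction_pct
control,ch2_rock,725,12,2.0
control,amide_III,1240,30,6.0
control,amide_II,1527,26,10.0
control,amide_I,1666,24,28.0
control,water_combination,2129,26,2.0
control,ch_stretch,2920,44,12.0
control,ch_unsaturated,3010,12,2.0
control,strOH,3300,56,31.1
control,syOH,3500,40,2.2
control,asyOH,3620,40,4.7
low_current,carbonyl_1929,1929,20,1.5
low_current,carbonyl_1821,1821,20,1.5
low_current,thiol,2490,20,1.0
low_current,ch2_rock,725,12,1.2
low_current,amide_III,1240,30,5.0
low_current,amide_II,1527,26,9.0
low_current,amide_I,1666,24,25.0
low_current,water_combination,2129,26,0.5
low_current,ch_stretch,2920,44,12.6
low_current,ch_unsaturated,3010,12,2.0
low_current,strOH,3300,56,33.5
low_current,syOH,3500,40,2.3
low_current,asyOH,3620,40,4.9
mid_current,ch2_rock,725,12,1.3
mid_current,amide_III,1240,30,6.0
mid_current,amide_II,1551,26,10.0
mid_current,amide_I,1674,24,28.0
mid_current,water_combination,2129,26,3.0
mid_current,ch_stretch,2920,44,15.7
mid_current,ch_unsaturated,3010,12,3.5
mid_current,strOH,3300,56,25.0
mid_current,syOH,3500,40,2.0
mid_current,asyOH,3620,40,5.5
high_current,ch2_rock,725,12,1.3
high_current,amide_III,1240,30,6.0
high_current,amide_II,1512,26,9.0
high_current,amide_I,1659,24,28.0
high_current,water_combination,2129,26,3.5
high_current,ch_stretch,2920,44,17.7
high_current,ch_unsaturated,3010,12,3.5
high_current,strOH,3300,56,24.0
high_current,syOH,3500,40,2.0
high_current,asyOH,3620,40,5.0
extreme,ch2_rock,725,12,1.2
extreme,amide_III,1240,30,7.0
extreme,amide_I,1674,24,30.0
extreme,water_combination,2129,26,4.5
extreme,ch_stretch,2920,44,27.0
extreme,ch_unsaturated,3010,12,4.0
extreme,strOH,3300,56,20.0
extreme,syOH,3500,40,1.8
extreme,asyOH,3620,40,4.5
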