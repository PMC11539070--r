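name,delta_d,delta_p,delta_h,molar_volume_cm3mol
water,15.5,16.0,42.3,18.0
methanol,15.1,12.3,22.3,40.7
ethanol,15.8,8.8,19.4,58.5
1-propanol,16.0,6.8,17.4,75.2
2-propanol,15.8,6.1,16.4,76.8
1-butanol,16.0,5.7,15.8,91.5
acetone,15.5,10.4,7.0,74.0
methyl_ethyl_ketone,16.0,9.0,5.1,90.1
ethyl_acetate,15.8,5.3,7.2,98.5
butyl_acetate,15.8,3.7,6.3,132.5
tetrahydrofuran,16.8,5.7,8.0,81.7
1_4-dioxane,19.0,1.8,7.4,85.7
diethyl_ether,14.5,2.9,5.1,104.8
dichloromethane,18.2,6.3,6.1,63.9
chloroform,17.8,3.1,5.7,80.7
toluene,18.0,1.4,2.0,106.8
benzene,18.4,0.0,2.0,89.4
n-hexane,14.9,0.0,0.0,131.6
n-heptane,15.3,0.0,0.0,147.4
cyclohexane,16.8,0.0,0.2,108.7
acetonitrile,15.3,18.0,6.1,52.6
dimethyl_sulfoxide,18.4,16.4,10.2,71.3
dimethylformamide,17.4,13.7,11.3,77.0
n-methyl-2-pyrrolidone,18.0,12.3,7.2,96.5
acetic_acid,14.5,8.0,13.5,57.1
formamide,17.2,26.2,19.0,39.8
ethylene_glycol,17.0,11.0,26.0,55.8
glycerol,17.4,12.1,29.3,73.3
propylene_carbonate,20.0,18.0,4.1,85.0
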