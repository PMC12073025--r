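analyte,conc_ug_ml,trueness_pct,trueness_pm_pct,repeatability_pct,intermediate_precision_pct
IVA,0.05,100.4,16,1.9,7.1
IVA,0.1,98.0,10.3,2.7,4.6
IVA,0.4,102.2,8,2.2,3.5
IVA,2.5,102.8,3.9,1.4,1.7
IVA,5,99.5,8.3,2.0,3.7
LUM,0.4,100.5,4.3,1.9,1.9
LUM,0.8,100.0,14.6,6.4,6.4
LUM,3.2,103.5,4.3,1.5,1.9
LUM,20,101.8,6.9,1.8,3.1
LUM,40,99.9,7.1,3.1,3.1
TEZ,0.1,99.3,10,2.4,4.4
TEZ,0.2,96.7,6.3,1.8,2.8
TEZ,0.8,100.3,9.2,3.7,4.1
TEZ,5,102.9,3,1.3,1.3
TEZ,10,100.2,5.9,1.4,2.6
ELX,0.15,102.3,8.7,1.1,3.8
ELX,0.3,101.2,8.2,3.6,3.6
ELX,1.2,101.4,5.8,2.5,2.5
ELX,7.5,102.9,6.7,2.8,3.0
ELX,15,99.1,9.7,4.3,4.3
IVA_M1,0.05,98.0,19.3,6.7,8.5
IVA_M1,0.1,97.7,18.2,8.0,8.0
IVA_M1,0.4,98.2,15,6.6,6.6
IVA_M1,2.5,103.3,10.9,2.8,4.8
IVA_M1,5,101.1,6.8,2.0,3.0
TEZ_M1,0.15,107.8,15.4,3.6,6.8
TEZ_M1,0.3,107.9,18.3,8.1,8.1
TEZ_M1,1.2,104.9,7.8,3.4,3.4
TEZ_M1,7.5,104.2,5.1,1.6,2.2
TEZ_M1,15,100.8,10.2,2.9,4.5
ELX_M23,0.15,89.8,24.6,4.0,10.9
ELX_M23,0.3,91.0,14.5,4.9,6.4
ELX_M23,1.2,102.2,13.8,4.9,6.1
ELX_M23,7.5,107.3,15.2,5.6,6.7
ELX_M23,15,99.2,13.3,4.0,5.9
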