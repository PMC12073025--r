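analyte,role,level,conc_ug_ml
IVA,cal,1,0.05
IVA,cal,2,0.10
IVA,cal,3,0.20
IVA,cal,4,0.50
IVA,cal,5,1.25
IVA,cal,6,5.00
LUM,cal,1,0.40
LUM,cal,2,0.80
LUM,cal,3,1.60
LUM,cal,4,4.00
LUM,cal,5,10.00
LUM,cal,6,40.00
TEZ,cal,1,0.10
TEZ,cal,2,0.20
TEZ,cal,3,0.40
TEZ,cal,4,1.00
TEZ,cal,5,2.50
TEZ,cal,6,10.00
ELX,cal,1,0.15
ELX,cal,2,0.30
ELX,cal,3,0.60
ELX,cal,4,3.00
ELX,cal,5,7.50
ELX,cal,6,15.00
IVA_M1,cal,1,0.05
IVA_M1,cal,2,0.10
IVA_M1,cal,3,0.20
IVA_M1,cal,4,1.00
IVA_M1,cal,5,2.50
IVA_M1,cal,6,5.00
TEZ_M1,cal,1,0.15
TEZ_M1,cal,2,0.30
TEZ_M1,cal,3,0.60
TEZ_M1,cal,4,3.00
TEZ_M1,cal,5,7.50
TEZ_M1,cal,6,15.00
ELX_M23,cal,1,0.15
ELX_M23,cal,2,0.30
ELX_M23,cal,3,0.60
ELX_M23,cal,4,3.00
ELX_M23,cal,5,7.50
ELX_M23,cal,6,15.00
IVA,qc_validation,1,0.05
IVA,qc_validation,2,0.10
IVA,qc_validation,3,0.40
IVA,qc_validation,4,2.50
IVA,qc_validation,5,5.00
LUM,qc_validation,1,0.40
LUM,qc_validation,2,0.80
LUM,qc_validation,3,3.20
LUM,qc_validation,4,20.00
LUM,qc_validation,5,40.00
TEZ,qc_validation,1,0.10
TEZ,qc_validation,2,0.20
TEZ,qc_validation,3,0.80
TEZ,qc_validation,4,5.00
TEZ,qc_validation,5,10.00
ELX,qc_validation,1,0.15
ELX,qc_validation,2,0.30
ELX,qc_validation,3,1.20
ELX,qc_validation,4,7.50
ELX,qc_validation,5,15.00
IVA_M1,qc_validation,1,0.05
IVA_M1,qc_validation,2,0.10
IVA_M1,qc_validation,3,0.40
IVA_M1,qc_validation,4,2.50
IVA_M1,qc_validation,5,5.00
TEZ_M1,qc_validation,1,0.15
TEZ_M1,qc_validation,2,0.30
TEZ_M1,qc_validation,3,1.20
TEZ_M1,qc_validation,4,7.50
TEZ_M1,qc_validation,5,15.00
ELX_M23,qc_validation,1,0.15
ELX_M23,qc_validation,2,0.30
ELX_M23,qc_validation,3,1.20
ELX_M23,qc_validation,4,7.50
ELX_M23,qc_validation,5,15.00
IVA,qc_routine,1,0.15
IVA,qc_routine,2,0.75
IVA,qc_routine,3,3.75
LUM,qc_routine,1,1.20
LUM,qc_routine,2,6.00
LUM,qc_routine,3,30.00
TEZ,qc_routine,1,0.30
TEZ,qc_routine,2,1.50
TEZ,qc_routine,3,7.50
ELX,qc_routine,1,0.45
ELX,qc_routine,2,2.25
ELX,qc_routine,3,11.25
IVA_M1,qc_routine,1,0.15
IVA_M1,qc_routine,2,0.75
IVA_M1,qc_routine,3,3.75
TEZ_M1,qc_routine,1,0.45
TEZ_M1,qc_routine,2,2.25
TEZ_M1,qc_routine,3,11.25
ELX_M23,qc_routine,1,0.45
ELX_M23,qc_routine,2,2.25
ELX_M23,qc_routine,3,11.25
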