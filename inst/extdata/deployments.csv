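year,tag,model,deploy_date,longevity_days,sex,length_cm
2002,10927,ST16,2002-07-13,21,Fc,320
2003,10899,ST16,2003-08-05,83,M,370
2003,10926,ST16,2003-08-04,112,Fc,375
2003,10971,ST16,2003-07-30,107,M,405
2003,10972,ST16,2003-08-03,117,Fc,344
2004,10978,ST16,2004-07-24,224,M,410
2004,10979,ST16,2004-07-24,268,M,400
2004,10980,ST16,2004-07-25,231,Fc,340
2004,40622,ST16,2004-07-26,71,Fc,408
2004,40623,ST16,2004-07-27,201,M,409
2005,10970,Splash,2005-07-23,37,M,330
2005,40153,Splash,2005-07-30,50,M,310
2005,57600,Splash,2005-07-30,213,M,265
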