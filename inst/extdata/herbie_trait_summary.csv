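population,period,trait,mean,minimum,maximum,cv_pct
Herbie,spring,Llength,316,97,509,22
Herbie,spring,LERmax,1.74,0.88,2.65,18
Herbie,spring,LED,274,165,355,11
Herbie,autumn,Llength,306,144,474,22
Herbie,autumn,LERmax,1.51,0.84,2.56,18
Herbie,autumn,LED,295,198,448,13
Cc,autumn,Llength,272,128,489,26
Cc,autumn,LERmax,1.48,0.80,2.56,22
Cc,autumn,LED,272,181,350,14
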