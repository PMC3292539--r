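population,period,trait,sigma2_E,sigma2_GE,sigma2_Period,sigma2_GExPeriod,cv_pct,H2
Herbie,spring,Llength,1176,4524,,,11,0.79
Herbie,spring,LED,658,700,,,9,0.52
Herbie,spring,LERmax,0.024,0.096,,,9,0.80
Herbie,autumn,Llength,1720,3668,,,13,0.68
Herbie,autumn,LED,1233,1003,,,12,0.45
Herbie,autumn,LERmax,0.028,0.063,,,11,0.69
Cc,autumn,Llength,1634,4477,,,14,0.73
Cc,autumn,LED,1557,836,,,15,0.35
Cc,autumn,LERmax,0.033,0.094,,,12,0.74
Herbie,both,Llength,1430,19569,55510,4467,12,0.55
Herbie,both,LED,928,4635,147004,1680,11,0.32
Herbie,both,LERmax,0.03,0.37,18,0.09,10,0.53
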