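component,lower,upper,points
respiratory_rate,0,8,3
respiratory_rate,9,11,1
respiratory_rate,12,20,0
respiratory_rate,21,24,2
respiratory_rate,25,60,3
spo2,50,91,3
spo2,92,93,2
spo2,94,95,1
spo2,96,100,0
systolic_bp,40,90,3
systolic_bp,91,100,2
systolic_bp,101,110,1
systolic_bp,111,219,0
systolic_bp,220,300,3
pulse,20,40,3
pulse,41,50,1
pulse,51,90,0
pulse,91,110,1
pulse,111,130,2
pulse,131,220,3
temperature,30,35,3
temperature,35.1,36,1
temperature,36.1,38,0
temperature,38.1,39,1
temperature,39.1,43,2
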