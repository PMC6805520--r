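,E1,E2,E3,E4,I1,I2,I3,T1,T2,T3,T4
E1,0.0615,0.0615,0.0615,0.0615,0.0615,0.0615,0.0615,0.0615,0.0615,0.0615,0.0615
E2,0.0587,0.0587,0.0587,0.0587,0.0587,0.0587,0.0587,0.0587,0.0587,0.0587,0.0587
E3,0.0050,0.0050,0.0050,0.0050,0.0050,0.0050,0.0050,0.0050,0.0050,0.0050,0.0050
E4,0.0089,0.0089,0.0089,0.0089,0.0089,0.0089,0.0089,0.0089,0.0089,0.0089,0.0089
I1,0.0520,0.0520,0.0520,0.0520,0.0520,0.0520,0.0520,0.0520,0.0520,0.0520,0.0520
I2,0.3409,0.3409,0.3409,0.3409,0.3409,0.3409,0.3409,0.3409,0.3409,0.3409,0.3409
I3,0.2052,0.2052,0.2052,0.2052,0.2052,0.2052,0.2052,0.2052,0.2052,0.2052,0.2052
T1,0.0955,0.0955,0.0955,0.0955,0.0955,0.0955,0.0955,0.0955,0.0955,0.0955,0.0955
T2,0.0318,0.0318,0.0318,0.0318,0.0318,0.0318,0.0318,0.0318,0.0318,0.0318,0.0318
T3,0.0346,0.0346,0.0346,0.0346,0.0346,0.0346,0.0346,0.0346,0.0346,0.0346,0.0346
T4,0.1058,0.1058,0.1058,0.1058,0.1058,0.1058,0.1058,0.1058,0.1058,0.1058,0.1058
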