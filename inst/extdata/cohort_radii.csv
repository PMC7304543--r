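patient_id,R0_mm,R1_mm,R2_mm
1,14.87,20.73,27.77
2,20.48,26.34,38.24
3,6.61,10.91,15.24
4,22.87,26.96,37.03
5,8.17,14.20,25.10
6,8.29,15.83,20.35
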