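peptide,pH,K1,K2,KII,dH_I,dH_II,dH_c
CaM Y I-II,6,3.5e7,7.4e6,3.7e6,-40.2,-2.0,25.0
CaM1 Y I-II,6,3.0e7,7.0e6,3.5e6,-26.1,-3.5,22.0
CaM YW I-II,6,7.4e7,9.7e6,5.1e6,-34.8,-8.9,3.8
CaM1 YW I-II,6,7.8e7,9.4e6,5.9e6,-26.1,-15.0,8.9
CaM1 Y I-II P,6,3.6e8,7.8e7,2.1e7,,,
CaM1 Y I-II P,7,1.0e11,7.1e8,1.8e8,,,
CaM1 YW I-II P,6,3.8e8,1.3e8,2.1e7,,,
CaM1 YW I-II P,7,6.0e11,5.1e9,1.8e8,,,
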