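site,E01,E02,E03,P01,P02,P03,P04,P05,P06,P07,P08,P09,P10,AI
A,18.2,22.6,16.5,14.3,15.0,16.8,17.0,19.1,29.1,18.6,20.0,14.0,19.1,8.9
B,13.6,18.6,9.5,7.8,13.5,11.4,18.0,9.5,20.8,10.0,12.3,12.6,12.7,10.6
C,9.2,10.1,9.0,8.7,11.9,11.1,8.3,9.0,10.1,8.6,7.5,10.9,6.5,8.9
D,10.2,14.9,12.4,,,,,,,,12.0,9.7,5.9,15.2
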