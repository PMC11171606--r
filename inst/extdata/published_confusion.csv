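cell,count
NN,10762
NT,2044
TN,3171
TT,17174
IN,2541
IT,1535
ULN,1408
ULT,1644
ULI,664
UPN,1678
UPT,1430
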