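name,multimer,mass_delta,charge,polarity
[M+H]+,1,1.007276467,1,positive
[M+Na]+,1,22.989218702,1,positive
[M+NH4]+,1,18.033825567,1,positive
[M+K]+,1,38.963158100,1,positive
[2M+H]+,2,1.007276467,1,positive
[M+H-H2O]+,1,-17.003288219,1,positive
[M-H]-,1,-1.007276467,-1,negative
[M+HCOO]-,1,44.998202851,-1,negative
[M+Cl]-,1,34.969401260,-1,negative
[2M-H]-,2,-1.007276467,-1,negative
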