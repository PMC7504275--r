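code,acyl_carbons,double_bonds
P,16,0
S,18,0
O,18,1
L,18,2
Ln,18,3
N,19,0
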