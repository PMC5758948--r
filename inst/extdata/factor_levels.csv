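factor,description,units,level1,level2,level3
A,ORWW portion in digester,%,33,44,55
B,temperature,degC,36,46,56
C,sonication time,min,15,30,0
D,total solids level in digester,%,6,11,18
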