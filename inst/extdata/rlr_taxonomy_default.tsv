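pattern	clade	label
		V2
CARD		C
CARD+CARD	lophotrochozoa	L1
CARD+CARD		V1
Death	lophotrochozoa	L6
Death		A1
DED		L2
CASc		L3
IG		L4
SAM		L5
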