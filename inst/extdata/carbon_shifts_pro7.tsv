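peptide	residue	atom	ppm
AVP	7	CB	29.46
AVP	7	CG	25.17
iAVP	7	CB	29.50
iAVP	7	CG	25.22
DAVP	7	CB	29.38
iDAVP	7	CB	29.20
iDAVP	7	CG	24.92
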