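peptide	residue	residue_name	J	chirality
AVP	8	ARG	8.9	L
iAVP	8	ARG	9.8	D
DAVP	8	ARG	10.2	D
iDAVP	8	ARG	11.8	L
AVP	4	GLN	9.1	L
DAVP	4	GLN	6.8	L
iAVP	4	GLN	9.9	D
iDAVP	4	GLN	6.5	D
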