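# Sample analysis config.  Sections:
#   [species]    residue name (as written in the file) -> species label
#   [directors]  SPECIES.chain = ordered head-to-tail carbon atom names
#   [terminal]   SPECIES = one terminal atom per acyl chain (2D statistics)
#   [selections] named selection strings (species/resid/name/chain, and/or)

[species]
POPE = POPE
POPG = POPG
CL   = CL
CDL2 = CL
UNP  = UNDP

[directors]
POPE.sn1 = C31 C32 C33 C34 C35 C36 C37 C38 C39 C310 C311 C312 C313 C314 C315 C316
POPE.sn2 = C21 C22 C23 C24 C25 C26 C27 C28 C29 C210 C211 C212 C213 C214
POPG.sn1 = C31 C32 C33 C34 C35 C36 C37 C38 C39 C310 C311 C312 C313 C314 C315 C316
POPG.sn2 = C21 C22 C23 C24 C25 C26 C27 C28 C29 C210 C211 C212 C213 C214
CL.ch1   = CA1 CA2 CA3 CA4 CA5 CA6 CA7 CA8 CA9 CA10 CA11 CA12
CL.ch2   = CB1 CB2 CB3 CB4 CB5 CB6 CB7 CB8 CB9 CB10 CB11 CB12
CL.ch3   = CC1 CC2 CC3 CC4 CC5 CC6 CC7 CC8 CC9 CC10 CC11 CC12
CL.ch4   = CD1 CD2 CD3 CD4 CD5 CD6 CD7 CD8 CD9 CD10 CD11 CD12

[terminal]
POPE = C316 C214
POPG = C316 C214
CL   = CA12 CB12 CC12 CD12

[selections]
mobile_loop = resid 61-81
rmh         = resid 1-36
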