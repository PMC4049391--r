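# Common restriction endonucleases: top-strand recognition motif and the
# cut position in bases from the 5' end of the motif (AT^CGAT -> 2).
name	recognition	cut_offset
ClaI	ATCGAT	2
EcoRI	GAATTC	1
BamHI	GGATCC	1
HindIII	AAGCTT	1
XhoI	CTCGAG	1
PstI	CTGCAG	5
SalI	GTCGAC	1
KpnI	GGTACC	5
SacI	GAGCTC	5
SmaI	CCCGGG	3
XbaI	TCTAGA	1
SpeI	ACTAGT	1
NdeI	CATATG	2
NcoI	CCATGG	1
NotI	GCGGCCGC	2
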