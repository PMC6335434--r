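# Acute-phase response proteins removed from Ig-bound candidate lists.
# Editable; symbols are HGNC gene symbols.
CRP
SAA1
SAA2
SAA4
HP
HPR
FGA
FGB
FGG
SERPINA1
SERPINA3
ORM1
ORM2
LBP
CP
F2
PLG
APCS
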