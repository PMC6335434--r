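# Classical high-abundance plasma proteins removed from Ig-bound candidate
# lists. Editable; symbols are HGNC gene symbols.
ALB
TF
TTR
HPX
A2M
APOA1
APOA2
APOB
C3
C4A
C4B
AHSG
GC
AMBP
SERPINC1
SERPING1
ITIH1
ITIH2
ITIH4
APOA4
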