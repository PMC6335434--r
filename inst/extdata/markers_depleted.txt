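# Endoplasmic-reticulum / mitochondrial / Golgi proteins expected to be
# underrepresented in exosome preparations.
CANX
CYC1
GOLGA2
HSP90B1
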