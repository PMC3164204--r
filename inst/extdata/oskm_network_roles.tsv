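POU5F1	source
SOX2	source
KLF4	source
MYC	source
MYCN	sink
OTX2	sink
ZIC3	sink
DNMT3A	sink
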