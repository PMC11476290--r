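type	n
EDIT_AI	16
FIVE_PRIME	213
NTA_A	128
NTA_U	100
miRNA	654
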