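P14174
P04075
Q14573
Q92597
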