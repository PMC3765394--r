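rheumatoid arthritis
rheumatoid arthr
rheum arth
rh arthritis
rha
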