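read_code,description
43F..00,Rheumatoid factor
43F1.00,R.A. latex test
43F2.00,Rose-Waaler test
43G3.00,Serum rheumatoid antigen level
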