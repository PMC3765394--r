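read_code,description
N040.00,Rheumatoid arthritis
N040000,Rheumatoid arthritis of cervical spine
N040100,Other rheumatoid arthritis of spine
N042.00,Seropositive errosive rheumatoid arthritis
Nyu1100,[X]Seropositive rheumatoid arthritis unspecified
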