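read_code,description
N045.00,Seronegative arthritis
N046.00,Polyarthropathy NOS
N094500,Arthralgia of multiple joints
N047.00,Inflammatory polyarthropathy
N04y.00,Other specified inflammatory polyarthropathy
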