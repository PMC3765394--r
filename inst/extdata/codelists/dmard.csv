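read_code,description
dh11.00,Methotrexate 2.5mg tablets
dh12.00,Methotrexate 10mg tablets
dj21.00,Sulfasalazine 500mg e/c tablets
dj31.00,Hydroxychloroquine 200mg tablets
dj41.00,Leflunomide 10mg tablets
dj51.00,Azathioprine 50mg tablets
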