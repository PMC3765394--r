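read_code,description
66H..00,Rheum. disorder monitoring
66H1.00,Rheum. treatment change
66H2.00,Rheum. management plan given
9N1r.00,Under care of rheumatologist
8H57.00,Referral to rheumatology service
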