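read_code,description
N094.00,Pain in joint - arthralgia
N093.00,Joint abnormal
N09F.00,Joint swelling
2G27.00,Joint stiffness
N095.00,Reduced joint movement
N096.00,Joint movement painful
N09G.00,Inflammation of joint
N094200,Arthralgia of unspecified site
N094B00,Wrist joint pain
N094700,Hand pain
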