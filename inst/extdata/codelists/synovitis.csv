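read_code,description
N065.00,Synovitis and tenosynovitis
N065z00,Synovitis or tenosynovitis NOS
N065200,Synovitis of wrist
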