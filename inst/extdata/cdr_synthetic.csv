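caller,callee,time,antenna_id
u1,u2,100,a1
u2,u1,200,a1
u1,u3,300,a2
u3,u1,400,a3
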