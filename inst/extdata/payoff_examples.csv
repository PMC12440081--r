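label,condition,a,b,c,d
synthetic-coexist,no drug,2,2.4,2.8,2.2
synthetic-neutral,no drug,1,1,1,1
synthetic-b-zero,averaged mice,1,0,1.3,1.05
synthetic-bad-a,no drug,0,1,1,1
synthetic-masked,drug,1,1.2,0.9,1.1
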