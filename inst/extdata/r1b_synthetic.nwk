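(t1:106,t6:108,(t3:131,t4:100,t5:123):1,t2:112);
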