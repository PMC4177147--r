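((t1:93,((t3:64,t8:72):4,(t4:25,t5:42):42):13):44,(t2:46,t6:63,t7:76):75);
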