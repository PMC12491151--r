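source_a	source_b	n_shared_instrumented
ukbppp	decode	999
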