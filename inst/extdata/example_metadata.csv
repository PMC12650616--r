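sample_id,label,batch
example_clonotypes_simple,CRC,batch1
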