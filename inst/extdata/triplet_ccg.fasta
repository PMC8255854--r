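>s1
CCG
>s2
GCG
>s3
CGC
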