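name,forward_primer,reverse_primer,display_order
SSR3,GCGAAACCATATTCATGCGT,ATTACTTGTCGTCGGCAGGA,1
SSR11,GGAGTTTGAGTTGAGGCAGC,ATGAACCAGACCAAAGACCG,2
SSR12,GGCACGGACATAGACCTCAT,GTGGTGGTGTGACGACGTAT,3
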