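accession,SSR3_a,SSR3_b,SSR11_a,SSR11_b,SSR12_a,SSR12_b
HM2,150,156,210,218,302,
HM5,150,,210,214,302,306
HM12,150,156,210,218,302,
HM29,152,156,214,218,306,
HM35,150,152,218,,302,306
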