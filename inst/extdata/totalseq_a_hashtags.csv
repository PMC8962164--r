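tag_name,tag_seq
HT1,GTCAACTCTTTAGCG
HT2,TGATGGCCTATTGGG
HT3,TTCCGCCTCTCTTTG
HT4,AGTAAGTTCAGCGTA
HT5,AAGTATCGTTTCGCA
HT6,GGTTGCCAGATGTCA
HT7,TGTCTTTCCTGCCAG
HT8,CTCCTCTGCAATTAC
HT9,CAGTAGTCACGGTCA
HT10,ATTGACCCGCGTTAG
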