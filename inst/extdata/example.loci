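sample_a  ACGTACGTACGTACGTACGTACGTACGTACGTACGT
sample_b  ACGTACGTACGTACGTACGTACGTACGTACGAACGT
sample_c  ACGTACGTACGTACGTACRTACGTACGTACGAACGT
sample_d  ACGTACGTACGTACGTACGTACGTACGTACGTACGT
//        |1|
sample_a  TTGCATGCATGCATGCATGCATGCATGCATGCATGC
sample_b  TTGCATGCATGCATGCATGCATGCATGCATGCATGC
sample_d  TTGCATGCATGCATGCWTGCATGCATGCATGCATGC
//        |2|
sample_b  GGGGCCCCAAAATTTTGGGGCCCCAAAATTTTGGGG
sample_c  GGGGCCCCAAAATTTTGGGGCCCCAAAATTTTGGGA
sample_d  GGGGCCCCAAAATTTTGGGGCCCCAAAATTTTGGGA
//        |3|
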