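>example_construct
TTCTGCTCTTCGGCCGAAGTGCAGCTGCTGGAAAGCGGCGGCGGCCTGGTGCAGCCGGGCGGCAGCCTGCGCCTGAGCTG
CGCGGCGAGCGGCTTTGATTTTGATGAAGATATGAGCTGGGTGCGCCAGGCGCCGGGCAAAGGCCTCGAGTGGGTGAGCG
CGATTAGCGGCAGCGGCGGCAGCACCTATGAGCTCGATAGCGTGAAAGGCCGCTTTACCATTAGCCGCGATAACAGCAAA
AACACCCTGTATCTGCAAATGAACAGCCTGCGCGCGGAAGATACCGCGGTGTATTATTGCGCGCTGCAGAGCGGCAGCTA
TGGCAGCAGCTTTGATTATTGGGGCCAGGGTACCCTGGTGACCGTGAGCAGCGGCAGAATGCAGTT
>example_gene
GAAGTGCAGCTGCTGGAAAGCGGCGGCGGCCTGGTGCAGCCGGGCGGCAGCCTGCGCCTGAGCTGCGCGGCGAGCGGCTT
TGATTTTGATGAAGATATGAGCTGGGTGCGCCAGGCGCCGGGCAAAGGCCTCGAGTGGGTGAGCGCGATTAGCGGCAGCG
GCGGCAGCACCTATGAGCTCGATAGCGTGAAAGGCCGCTTTACCATTAGCCGCGATAACAGCAAAAACACCCTGTATCTG
CAAATGAACAGCCTGCGCGCGGAAGATACCGCGGTGTATTATTGCGCGCTGCAGAGCGGCAGCTATGGCAGCAGCTTTGA
TTATTGGGGCCAGGGTACCCTGGTGACCGTGAGCAGC
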