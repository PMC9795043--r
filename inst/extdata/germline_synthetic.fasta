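>IGHV1-S1
CACTGTAGGTCCTTTAGGTCACCAACCTCTCTCGGCGATCGGCCTGTCTTCCGAATACTGTTTGCATGTAATACGGACAGTAGCCTCGTCCTCCTAAGTCGCCGACGGACGAACTCTCTAACGGCCTCAGGGCAGTTTAGGATTTGGACGCACCAACTGACAGAAGACAATACCTGTTATGGAGTGAAGTTAAAGCTATATCGAACCCACGATGGACGAAGCGCGGTCGCGGTCGTGGTGTATTACTGTGCGAGAG
>IGHD6-19S
CAATGGCTG
>IGHJ4S
AACGACTACTGGGGTCAAGGAACCCTGGTCACCGTCTCC
>IGHV1-69S
TCGTGTGGGAATTTCGGTATGTCAGATGAGGGACCCCTTTATGATTTCGCGACTATCTTCGCTCCACACCAACCTTCGAACACGCAGGCGTGCGTGCATGCCTGTAGTGGAAAGTTGATAGTTTTTCTCGATTGCACTATGAGGGCCTGTGCCCTATTCCTGTCGTCACAGGTCTCCGTTCGAGTCGAGCTGGGTATATGTAAAACGGCACATCTCCGACTGGACGAGCGAGCGCTAGTGTATTACTGTGCGAGAGA
>IGHD3-16S
GTATTATGATTACGTTTGGGGGAGTTAT
>IGHJ3S
GCTTTTGATATCTGGGGCCAAGGGACAATGGTCACCGTCTCT
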