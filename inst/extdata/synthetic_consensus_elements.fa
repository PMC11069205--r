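>AluYa5 synthetic consensus-like SINE/Alu body (282 bp)
GGCCGGGCGCGGTGGTGAGCGCCAAGCCTACGGTGACCCACAACGGCTGCCTTCAGCTCGTCCCCGCTCGGTGCACCGGAGCAACTGCTCTAGGCTGCCATCGCTGAGCCGACTCTCCCCGCGGGACGGCCTCCTGTGACCGGCCAGTGAGCCTGGGGTCGGTGCTGCTGGGTACGCGCTGCAGAGCGAACGTCGCCTAACTCAATCATACCGGTCACCTACATCGCACTGGCTATGCCGGTTCATGGCCCAAAGAGATCTTGGCGGACGGGCCGTGCCGTG
>AluYb8 synthetic consensus-like SINE/Alu decoy (289 bp)
GGCCGGGCGCGGTGGTGAGTTCCAAGGCTATGGTGAGCGACAGCAGAGGCGTTGTTCTCGTCCCCGTTTGGTGCACTGGAGCTTCGGCTCTAGGCTCCCATCGCTGTGCCGACTCTCCCCGGGGGACGTCCTCCAGTGGCCGGCGAGTCAGCCTGGGGTCGGTGCTGCTGGAAACGCGGTGCAGAACAAACGTCGCTTAACTCGATCATACCGGGCACCTACATCGCACTGCTTATGCCGGTTCATGGCCCAAAGAGATCTGGGCTGACGGGCCGGGCCCTGGGGCCAC
>L1 synthetic LINE/L1 5prime fragment decoy (400 bp)
AAATCGTGTGCCGTTGTACTTAAGCTTCTTAAATGTTTGGTTCGGAGTTACATGTCGATGATGCGTTTACTCAGCATTATTACGCACCATCTCAATGGACGAGACTTACATATCAAACTTTCAGATAAATTTAAAGAGGAAGTAACCCACTATTTATTTACGAGCTTGGGTTCAACAATAGCAGCCGCACCTGTATTAAGAAATGAAAGCCTAATTTTACAACCATCGACGGAACTCTGGATCGTAGTTCGACTATGTAATAGAATTTCATGTAGACGCTATTTAAAAAAGCTCAGTAACTCCCCTAATCTAATTCACTAACTCGATATTATACCCGCGAATGTCTTATTCTCCTATCGCCGGGAATGGCAAGAAATCAGTGCTTGATTTCGTACGTCTC
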