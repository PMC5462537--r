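>chr5 synthetic connexin-style locus
TTCCTGCCATAGGAGGGCTGCAGGAGGTTCTTCAAAGAATACTTCCAATTGCGCATGGGGGGTCACCCGA
GGGTTCGCTTTTCTTCCGGATCAGCAGATAATGACTACAATCTATATGTTTCTTGTGATGAGCGCGACAT
TTACCAGCGAGGATTGGCCAGGGGGCGCTCTGCAGATCCATTTTATGGCGCCGTGCCGGGTAAGAGCCGT
TGTGCGCTCAATTCAGGTAGCTGTCCAACGCTCCCAATTTTCCATCTTCTCGCGGATGAATCCATAATAT
GCACGCGCAGTCTGTTGGTGCCAATGAAACGACACCAATGTTAGCCGTCTTCGTCCCCGGGCCGAGTGAT
CAATCAGCCTCACCCCAGGTCGCCAGCAGTCAATCGACAAGTGTTCCCTATGTCGGACCAAGATGTGGTC
GGTTCGGGGCGACCGAGGCACCTGACGTGGTCAACATCGCCGATGTTATCTCTCACTGACCAAATGTTGG
TGGGCCAGTGGTGGATCCACACTTATCTATGGACCTCGGTTGCCAAGCAACTGTCTGGATCATACGCTGC
ACCCATACGTCTCGAATTCTCGCAAAAGAGCGGCGGCCAACGATATCGAAAAGCTGGCGCTTTGGCGTTT
AATGGGGCCGACACGCGGGGCAACAATTAAGCATCAGCTACTTGCTGCCATATGCGGGACCGAACCTTTG
CATCGCGTGGAGTAAGTCGGAACTCTATCTCGACCGCTTATCTCGATCATGGAGTGTGAT
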