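>cer
CTGGTTTATTCTGTTAACGAGTACCAAGGGCAGTACACTGCCATTCTAGGAATTGATTTAATTTATCCGAGAGTTTACGA
AATGCTCAACCCGAGATTCTTGATCTTGGGAGTTTCAACACAGAGGTTTTCGATGGGATTCTATTCTATTTATAGTAGCA
TGCAGGAGTACGTCTGTCGTTCTGAGGTTACAAAGATCCCCAAGCTTTATACTTTAGGAAATCTCCTCATAAAAGTCTTC
>par
CTGATGGACGCGGTTCACCAAAACCATCAGCAGCAGACTGCCATCTTGGGAGTTGATTTAATTAACCAGAAATTTAAAGA
TGTGGACAACTCGAGCGACTTGATTTAGGGATCATTCACACAGAGGTTCTCAGTAGAGATCTATTCTATTTTTAGGGGCG
GGAAGGAGTACGTTTTTAACTCTTATCTAACGGAAATCCCCTAACCTTATGTTTCAGGTAATCTATTCAAAATAGGCTAC
>mik
CCGGTATATATTGGTCGGCAGAGCGATCTATTGCGGACAGCCACCATCGAAGATATCAAAACGTGCCGCAGAATTGAAGA
AATAGTCAATCCGAAAAACTCGATACAAGGATTATCCATGCAGAGACTTCTTTTAGGAATTCGTTCTATTATCAGAGATA
TGCAGCAGTCCATCCGTAATGCGGACGGAGTAAAAATTCCCAAACTTTGCCCTTTTGGAAAGCTACTCACCGCGACTCGA
>bay
CTTCTTTATATTTCTCAGAAAAATAACTTACAATGTACAATCTTCTTCGGAGA------AGTTGACTTGGGG------TA
AGTATCCGACCTGTATGTCCTAATACAAAGATCATGGAGGTTGTAATTGCTGATGAAAAACTTCTCGATATTCCATGAGT
TACAAAGGATAAGCCTAAGAAAAGACGAGATGAAAGGTGTGGTTCGTTACACTACTAAAAGTTTACCTCTCTCAGCTACC
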