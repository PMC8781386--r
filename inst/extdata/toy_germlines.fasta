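>TOYV1-1*01
TTCACGAGGGGACTGAGGATAAAGGGTACTCGGTGTCTACGGGGACTTACTCGTAGAGCTCGTATACCGTTTTGTACCAAGGTTCTGCGAGTACAACCACGACCAAGCGGTGCACCAGACCACGAGGGAAGTGGATTGTCAGCAGAGGCGCTACCATTACAGACTCAGGAGGTGGATCGTGTGTTACAGTTTTCCCCATATCTCTGGCTAAGCGCGACTGGTGTGGCCAGATCTCTATCCTTACAGATGTGTCCCATTCAGTATGGGTTACGGGGAAGCCCAGGGCTTCTAACAGTTCTG
>TOYV2-1*01
TCGTATCCAGTAGATGGCCCTAGCACTCCCTGCCTGTTCAAGCTAAGGTCCTTGATCCGCGTGCTCGTAGGCTGGATAAACACCGGCGAGGAATTGAACATTGGGAGCCTTTGTTATCCGGTCTTCAAATACCCCCGTACTGTGGGCGTTTTCAGCCGCCCGATTGATATGTTCACCAGGACGGGTACGCGACCGACTGTGGACGAACCGACACTAATCAAGCATCCGCCTTTCTGGTACTTTGCCGAGATGGCTGAGTTTAAAGACTCGCTAAGTTCTTCTTGTAACTTTTTACTTCAA
>TOYV3-1*01
CAATATCGAGACCGGGGAGCGTTGCGTAGAACACCCCAAACCACGCGGGTGCTTACGCAGTCGCGTTCGGGCGGAGTGTGGTCCTTTATTTGCGGTAAGTACAACATCCAGGGAATGTATTGCGCTGCCGGCGCAGTGGGAATGGCCTCTATAACGCAGGTCTATCAGTTTTGGATCGCACGTTGCAGACGGTCATACGGCAGCCCCGCGATTGGTGATTGTACTCAGCTAACGCCATCAGAAAGTGGTCACCCCGCGCTTAGACGTGTATTTTGTTGTATTTTGGCTAAGGCCACTAAA
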