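>TauMiRNA166 tau-targeting amiRNA construct (MAPT exon 2/3 junction guide)
ACCGGTGTCGACTTTAAAGGGAGGTAGTGAGTGGACCAGTGGATCCTGGAGGCTTGCTGAAGGCTGTATG
CTGAATGCCTGCTTCTTCAGCTTTGTTTTGGCCACTGACTGACAAAGCTGAAAGCAGGCATTCAGGACAC
AAGGCCTGTTACTAGCACTCACATGGAACAAATGGCCCAGATCTGGCCGCACTCGAGATATCTAGAATTC
ACTAGTGAGCTC
>TauMiRNA724 tau-targeting amiRNA construct (MAPT exon 11 guide)
ACCGGTGTCGACTTTAAAGGGAGGTAGTGAGTGGACCAGTGGATCCTGGAGGCTTGCTGAAGGCTGTATG
CTGTAATGAGCCACACTTGGAGGTGTTTTGGCCACTGACTGACACCTCCAAGTGGCTCATTACAGGACAC
AAGGCCTGTTACTAGCACTCACATGGAACAAATGGCCCAGATCTGGCCGCACTCGAGATATCTAGAATTC
ACTAGTGAGCTC
>ScrMiRNA scrambled-control amiRNA construct (mixed-case record)
accggtGTCGACTTTAAAGGGAGGTAGTGAGTGGACCAGTGGATCCTGGAGGCTTGCTGAAGGCTGTATG
CTGAAATGTACTGCGCGTGGAGACGTTTTGGCCACTGACTGACGTCTCCACGCAGTACATTTCAGGACAC
AAGGCCTGTTACTAGCACTCACATGGAACAAATGGCCCAGATCTGGCCGCACTCGAGATATCTAGAATTC
ACTAGTGAGCTC
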