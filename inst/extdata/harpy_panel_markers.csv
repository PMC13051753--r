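locus,motif,n_repeats,primer_forward,primer_reverse,expected_size,annealing_temp
Hha01,AC,10,CTCCTGTGTTCCCATCTGCT,GGGTGCGAGACAGTTCCTC,158,59
Hha02,AC,10,TCTGTTGGAGTTTCCGGAGC,CCGGGATGCATCTCCTTTGT,192,59
Hha03,AG,14,ATGGCAAGTCGCTAGAACGG,GGCTGCTATTCCACTTGCCA,204,57
Hha04,AC,12,GTGGAAGGGAGTTAGCGTGG,ATGGCTCTGTCTAACCTGCG,125,59
Hha05,AGC,11,ACAAGGTCACATCTTCCCGC,AAACTGTTCTGCCTCGCTGA,179,59
Hha06,AG,12,ACCAGGCTGTAAGGGTTGAAG,TGGACAGATGTGGAGTGTCG,121,59
Hha08,AC,10,CATCCGTAGCCATGCACAGA,CTTACCTGGGTGTCAGCACA,155,57
Hha09,AC,12,ACCCAAGCTCTTCCTGGATG,TCAAAGCGTATGAAGCCAGGA,198,57
Hha12,AG,11,TCCTCCTTGGAAGCAGCAAG,AGCTCAGTTTCTGGAGTCAGG,120,57
Hha18,AC,11,GCCCACAGAAACGATACAGC,ATTAGCTGCTCGCAGACAAA,150,57
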