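>IGHV1-8*01
GAGGTGCAGCTGTTGGAGAGCTACGCTATGTGGGTCCGCCAGGCTCCAATTAGTGGTAGTTACTATGCAGACTCTGTGAAGTGTGCGAGAGA
>IGHV3-23*01
CAGGTGCAGCTGGTGCAGGGCTACACCTTCTGGGTGCGACAGGCCCCTATCAACCCTAGTTACGCACAGAAGTTTCAGGGCTGTGCGAGGGA
>IGHV4-59*01
GAAGTGCAGCTGGTGGAGGGATTCACCTTTTGGGTCCGTCAGGCTCCGATTAAGCAAGATTATGTGGACTCTGTGAAGGGCTGTACGAGAGA
>IGHD3-10*01
GGTATAACTGGAACGAC
>IGHD2-2*01
GTATTACGATTTTTGGAGTGGT
>IGHJ4*01
ACTACTTTGACTACTTGGGGCCAGGGAACC
>IGHJ6*01
CTTTGACTACTACTATGGGGTCAAGGAACT
>IGHM*01
GGGAGTGCATCCGCCCCAACC
>IGHG1*01
GCCTCCACCAAGGGCCCATCG
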