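>insert399 399-bp duplex insert with 11 binding sites and Drew-Dickerson dodecamer
GGATCCGGCTGAAGGTACAGACCCTTTAGTCAGTCTAGGATCATATGCCCAAACGGAACC
CCAGCTGTGATTTATGGCGTGGTTACATGTAAAAATTTACATCTTAGACCCACATTTGAA
AGGCAAATGGAGTACGTGTTTTTTAAAAAAATGTCCACGGGGGTCCTATAGAACTTTCCC
ACAGAGTATAGTACAAACTTTCTTGTATATAACTCACTAATTGAAGGCGCGAATTCGCGG
TATGCAAATAAGGGATGCGTCCTCATGTATATACATGAGGAAGCGTGTTAGCTGTCATAA
AGTTGTCACGGAGCGCAATTACCTAATAGGGAAATTTACACGCTAGGGACGCTATTATCG
CTATTAGTATAGCACGATACACGAAAACGCAGGAAGCTT
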