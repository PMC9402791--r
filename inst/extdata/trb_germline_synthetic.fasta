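>SYNV1 functional=yes
AGGACGCTTTCCGCCATTTCTCTGCTCGCATCGCACATAGCCGCCGAAGAAACATATATTTGTCCAGAACCGCGA
>SYNV2 functional=yes
AGCACTGAGACAATATCGGATTATGAAAGTGCACGTCTACTTGGTGGTTCGATGTACTTCTGTTCAACCAGCCAA
>SYNV3 functional=yes
ACACAAAGTGATTATTTAATAGTGTTGGGATTCAGGACACCTGTCAGCGCTAAGTATATTTGTTTGTTTGTACGG
>SYNV4 functional=yes
AGCAAGCGCAGGGCTTCCTCACTGACGCGGAGCATTGAACTCCCGTTGGGATATTACTACTGTTCACTTCCTATC
>SYNV5 functional=yes
CCTTCAAACGATGTGGCAGTTATGTCTGCCGCCAGGCTTGACCTGAGCGTAAGGTACATTTGTTCGAACTCAGGA
>SYNV6 functional=yes
CATCCAAAGTATAGACTTGACCATAGGACGCGTGGTGGAACGATCACTCGGCCTTACCTGTGCCCTGGCACGGGA
>SYNV7 functional=yes
TTAGTCGCAATGCAAATCAAAACAACACTGGCGATGTCACTGTACACTCCTCGTTACTTCTGCTACAGGGTGGAG
>SYNV8 functional=yes
ATCGTCCTATTCCCATCATTACCGCCTCCGCACAAACGTATAAATCGTACATATTACATCTGTGCTGCCTCCACC
>SYNV9 functional=yes
CTTACGAACAAGAAGGAAGGGTCAAGCATTAGTCTCATTTGGGGGATATCAACGTATTTTTGTTTTATAGAGTCA
>SYNV10 functional=yes
CGTGAGGTACAATTAGGTGTACTCAGCAGTCTAGGTTCGTGGTCCCAGACGATGTACTATTGTGTATTATTAGAT
>SYNV11 functional=yes
TCCACCAGCTCCTCCCCTCTACCCAGACTTGGCAAGATGCTTTTGACGAAGTTCTACATTTGTACATGGGTGCTG
>SYNV12 functional=yes
GTCCTAACAAAGGTAAGTGCTAATTTATATCTTAGCGTAACCGCGCGGGGGGGGTACTTCTGCTCCGCTAGTGAT
>SYNJ1 functional=yes
ATCGTATTCGGTCTGGGCACCATTGGATGGGTCCATCCTCGTCCC
>SYNJ2 functional=yes
CTTATGTTCGGCCCTGGCACTTTTCCATGCAAGGCTTACGCTACC
>SYNJ3 functional=yes
AGAGTGTTTGGAAGGGGGACCAAGCTAAATACGTCGTGGCCTCCT
>SYNJ4 functional=yes
TGGCCATTTGGGCAAGGAACAAGGGGAACACACTCCTGTACAGTT
>SYNJ5 functional=yes
TCGAATTTCGGTGAGGGGACTTCCTCGATCCGCGTGACAAACGGG
>SYNJ6 functional=yes
TCGCTGTGGGGCCCGGGTACAGAATTACAACCTGACGGCGGGTCG
>SYNC1 functional=yes
CACCATCCGCCGACATCGGATCCC
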