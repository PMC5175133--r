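>DEPDC1-F
GAAGCAGTGGATTGGCTTTATG
>DEPDC1-R
CCCACCTCCCTTTGATATCTTC
>DEPDC1B-F
GGAAATTCTGAAAGTCCCTTTGG
>DEPDC1B-R
CCATATCAGCTCCTGGGTATTT
>DEPDC2-F
GAGCACAAAGCCAAGAGAGA
>DEPDC2-R
TCCTACAGCATGCACAACAG
>DEPDC3-F
GCAGAGAAATGGTGGAACTCT
>DEPDC3-R
CTCCTGGTGCTACAGGAAATAC
>DEPDC4-F
GAACCGTAGAGATGGCTTCTG
>DEPDC4-R
GGGCCTGAAGAGAGTGAATAAT
>DEPDC5-F
CTCCTGTGGCTTCTTGTTAGT
>DEPDC5-R
TGATGTTGAGTGGGATGAAGAG
>DEPDC6-F
TTGTGGTGCGAGGAAGTAAG
>DEPDC6-R
CCGTTGACAGAGACGACAAA
>DEPDC7-F
ACCTTCCACTTCTTGACTCCTTAC
>DEPDC7-R
CGAGAGCCACTCATCTTCCTG
>ACTB-F
CGTGCGTGACATTAAGGAGAAG
>ACTB-R
GGAAGGAAGGCTGGAAGAGTG
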