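>clade1_leaf1
LRAEVCGMNITNLIEPYKWKCSNQPCQPGARPWYMVHQCVNIPLPQCHQWEESDKNQHYT
SWDGHVYEDTFLWMIEYCNHLMVPVQLHAMQYDCCKFMNWPMDNMRLRLYFEDETVIMNS
>clade1_leaf2
LRAEVCGMNITNLIEPYKWKHSNQPCQPGARPWYMVHQCVNIPPPQCHQWEESDKSQHYT
SWDGHVYEDTFLWMIEYCNHLMVPIQLHAMQYDCCKFMNWPMDNMRLRLYFEDETVIMNS
>clade2_leaf1
HPQWFRCCDIDALHCVYSWYHSNMPCWIQSDMDYMVYFCVNMPHIKWCSQKIKYRNRYSK
LWITWVFFRIFLFGFIYVNHEKVKIWNCTDRYRQQNFAWWPGDIERLRLWLVEEQVTELS
>clade2_leaf2
HPQWFRCCDIDALHCVYSWYHSNMPCWIQSDMDYMVYFCVNMPHIQWCSQKIKYRNRYSK
LWITWVFFDIFLFGFIYVNHLKVKIQNCTDRYRQQNFAWWPGDNERLRLWLVEEQVTELS
>clade3_leaf1
PPLYHCCCDITSRVCCYSWHEMKQDCENQADPDYMRWDSVNIPTTQCSMQFPAPRNREDE
LPYVIVFEHIFMDMIEIVNHSTVRIQANTDQYNCVNFAWWPETNTRTRLDDATEMVTLLS
>clade3_leaf2
PPLEHCCCDITSKVCCYSWHEMKQDCENQADPDYMRLDSVNIPTRQCSMQFPAPRNREDE
LWYVIVFEDIFMDMIEIVNHTTVKIQANTDQYNCVNFAWWPETNTRTRLDDATEMVTLLS
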