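>fam1 synthetic
ELEEYEDCKKHWCTFGDKGRPDDEGNEKNLDNRIVRKRERRGPDCVELILMHDRHNIKMK
TKMTKELRVPHHRYFRDDRELLRIHRVIRDTEGIRTRMRSPNNRRQTFKQEHIPDYH
>fam2 synthetic
RRDAKHEECQVYPRLKGRQSAPFHPRLMDCDFTRTPVKKPFGDVRRIKEAKRIKSQVRSE
DWKKNIDDRQCDRWAKQWMRTDDMRQWHKEPQYPMK
>fam3 synthetic
WLCISWYQPSEHGRDKDFVFGIFKALRAWMTCHEWRWKQLWERSHVKEVKKKDDGGDTEY
NGMLEIQPEFNTHMM
>fam4 synthetic
PKAVDDVKEDTLPDTDKGSEYHYRRENCLRDAQKFLKKGKECNILKGIQQVVIQVLKKCW
KICKITCDGRGKTKRPAHNDDVH
>fam5 synthetic
DEVHGLDQICLDPRASYQKRFCIRTQYHKNIRSKLEDRDRKIKRSSTDRCDLYYDARDID
KRHRFLVMVLDMKKGKLKQWEMRYIFLDERVKE
>fam6 synthetic
HCHCWVKNSDIETTAGCEYSKLGIPNETRYNHGDISYELRDASQDWDRHLVDEVHKKRKG
TWEPMRDDWRREDMAQSRRLHDKIEGIKRDDPKKHWLKLSWPEAYQ
>fam7 synthetic
AEIKGLWFTTGFYYQMWDTRCVLEPRERKATASSQFERPYIPREWFYRDDACRDQFRTCN
RMAVHKVKVNRFFKWHYWKFYFKKWRSEKM
>fam8 synthetic
FKTCEWEGADEEEHTQPERDIDDGEGRMGAHQFRNLIRGKDKPCTHMEDQVCKWCEYASH
EMNWLRQWDSELQLWEKVEQWNDDIHERDANPKM
>fam9 synthetic
IWQQQFDSRYFCDGMCPYHTEDKAEPGQEMNEAGEDKWNKKCAEKCCMETAKEEYADKRS
IYAW
>fam10 synthetic
LQRYDRKRVDQHERSVMRTWTIKDDNKKGSVQHRTSIYEITRPFEQDEDTPYRACTTSLH
WLCLMKWKKIGEEDAEKDARWILGGDRQEPEEIFG
>fam11 synthetic
HMMGDKRFEKKDNRREDKETPEMQMQRHSIYHVHFFFSYDKNLEAHCKAFNDGYKRVPHF
HDEEEMLHWEIEAAAFISETPAIWKATSRIMIGSEHIQSMGCNNPFPPWWVWK
>fam12 synthetic
PKEIRDAEENSWAYPNAKRQHEGDDSNWGRVCFSDNIKRRPRRHCEDQMKGVNQDEQRYG
YMRTDTWD
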