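>bg1 synthetic
VYHFCFQCCKVKKHLMNREGTDSGHNFLRGWWVQYRVKKPNAFVDKCFTKKLIPAPPQVS
L
>bg2 synthetic
PHFETKTISQKIATSFVNWEGSHDWKERFFKPMTKIIMVMWRSAFEMTHSDDPLRQYRWV
YVRPRTPVGAFCWVQWPHVPSIPLWM
>bg3 synthetic
HTEDKRRDLHNNEKLNWAMQVHLTWEHLFSQHFHVNPHVKKVRCGGLAFGAGNVAQHDNH
TCLRQREKYFNF
>bg4 synthetic
PHFTREPDFLIMIQMWVLDTIRSDADQYFLFAYCAMETHQHGCWWKVWEQPVREPSFWFG
LY
>bg5 synthetic
YFDTFTCVNHFSCYPVSPKAISRTVQQCCGQQQYCMWDCIPTHHIVFRYEHVTQHKKDII
KWTWTGGEPDAHGKDLDHGNKCIQFDMASHW
>bg6 synthetic
WSYEKMATRGRNQFTFRIDGFYCHMNYFDCFLAAPSDRVPNNQRMTNVFYNYYFKRYRID
FSVKEEVCHYRSIEIHQKAEERLLIHSLCTGEDMIVYMHYFSPLLMSKS
>bg7 synthetic
MCRSHKAQVMVYIKMFNSSGLNRHNAPKEVERPSAHHYINMLQDNTMCARMPCERHSILL
IWIAVHHTYLANLFREFCLRWSCLAD
>bg8 synthetic
FIVSNHCGMVRTCLHMKQTDFHVVDFFPFCLFAYTHLTSCAKNCQDPYVQTHERLPEQQR
GLCHSWIHDPPSGNSYNLRYTAYCWTHAFGNTMSCVKIKTKM
>bg9 synthetic
GILFDPSQWWALPDEPMEEYMKLDSPLSMKQVPEDGQECRTFCGLRALWSEFRMQPRPTV
RLHNYTVAMSCSLTAEANFE
>bg10 synthetic
ECIAPMHNYYDKLPVWMSMNMDADYDDCWFWEMYGIGILMNTDQDMQGPGPFLPHTALWY
YWFPRQDPWEVQNIKGWQKWSCFNDPPNMDKKFEPGCM
>bg11 synthetic
QSTPQQFQTQCEHGHCCMTLKIPSMHIWYNRTRTMRTLLRATICDIFPVSVNHSVIRMAQ
QEEVRITLTYCQQIPPWIKQFQCILQYKFWYH
>bg12 synthetic
ASAACKHTQCLMAGEYVKLHWVTADDMYPFSACKIWHYIVSHCCNPIEDFVLNPPYNHQA
ITLPFDCTQSDPLGKTHITKCSNFQRNMGRLADADKRIWQRSRHLFEMWVE
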