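>Proteinase-1
NLDLLDNSTG
>Proteinase-2
LMPCSMSS
>Proteinase-3
PSPVSSHPLAASVSGPC
>Proteinase-4
MRELVSM
>Proteinase-5
RNDIAESSCLVA
>Proteinase-6
ISRDSIPILF
>Proteinase-7
QAVVPMNTF
>Proteinase-8
QLGDGPLGGGHVDHIPF
>Proteinase-9
ARDLPRRF
>Proteinase-10
EVVILQ
>Trypsine-1
IPFVSGLMNAQIILFSGPCMIGRNAAVSCK
>Trypsine-2
ARTVFLNVRPGWSR
>Trypsine-3
EGQAQRTCAYPSAGLLQASQGR
>Trypsine-4
PCSRTSGSGACSGR
>Trypsine-5
NRTRVYTMPGWR
>Trypsine-6
LKSPPGLRK
>Trypsine-7
VARGEDATCPNDKGSEPR
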