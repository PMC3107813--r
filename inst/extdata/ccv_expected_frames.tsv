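peptide_id	peptide_seq	genome_frame
Proteinase-1	NLDLLDNSTG	+1
Proteinase-2	LMPCSMSS	+1
Proteinase-3	PSPVSSHPLAASVSGPC	-1
Proteinase-4	MRELVSM	+3
Proteinase-5	RNDIAESSCLVA	-1
Proteinase-6	ISRDSIPILF	+3
Proteinase-7	QAVVPMNTF	-2
Proteinase-8	QLGDGPLGGGHVDHIPF	+3
Proteinase-9	ARDLPRRF	+2
Proteinase-10	EVVILQ	-1
Trypsine-1	IPFVSGLMNAQIILFSGPCMIGRNAAVSCK	+3
Trypsine-2	ARTVFLNVRPGWSR	+3
Trypsine-3	EGQAQRTCAYPSAGLLQASQGR	+3
Trypsine-4	PCSRTSGSGACSGR	-1
Trypsine-5	NRTRVYTMPGWR	-2
Trypsine-6	LKSPPGLRK	-1
Trypsine-7	VARGEDATCPNDKGSEPR	+3
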