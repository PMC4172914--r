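mirna_id	fold_change	style	sequence
rno-miR-296-star	601.8687077	up	AGGGCCCCCCCUCAAUCCUGU
rno-miR-183	311.2671462	up	UAUGGCACUGGUAGAAUUCACU
rno-miR-130b	73.88701805	up	CAGUGCAAUGAUGAAAGGGCAU
rno-miR-298	73.54126053	up	GGCAGAGGAGGGCUGUUCUUCCC
rno-miR-199a-5p	39.0786033	up	CCCAGUGUUCAGACUACCUGUUC
rno-miR-106b-star	38.46729557	up	CCGCACUGUGGGUACUUGCUGC
rno-miR-323	37.0342188	up	CACAUUACACGGUCGACCUCU
rno-miR-301b	36.10785966	up	CAGUGCAAUGGUAUUGUCAAAGC
rno-miR-342-5p	19.28817847	up	AGGGGUGCUAUCUGUGAUUGAG
rno-miR-19a	18.83546833	up	UGUGCAAAUCUAUGCAAAACUGA
rno-miR-18a	18.76863728	up	UAAGGUGCAUCUAGUGCAGAUAG
rno-miR-487b	18.75103727	up	AAUCGUACAGGGUCAUCCACUU
rno-miR-20a	18.57354895	up	UAAAGUGCUUAUAGUGCAGGUAG
rno-miR-344a-3p	18.35504823	up	UGAUCUAGCCAAAGCCUGACCGU
rno-miR-431	17.97658408	up	UGUCUUGCAGGCCGUCAUGCA
rno-miR-301a	17.94604464	up	CAGUGCAAUAGUAUUGUCAAAGC
rno-miR-29c	0.071923249	down	UAGCACCAUUUGAAAUCGGUUA
rno-miR-29a	0.035852454	down	UAGCACCAUCUGAAAUCGGUUA
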