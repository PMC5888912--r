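species	ACT_P	ST_MHC	TPM	TNNI	TNNT	TNNC	TMOD	ACTN	CANA	CANB	CAPZA	CAPZB	MLIM	FHL	TTN	RYR
Saccoglossus_kowalevskii	0	1	1	0	3	0	1	1	1	1	1	1	2	1	1	1
Ptychodera_flava	0	1	1	1	4	0	1	1	0	1	1	1	1	1	2	1
Strongylocentrotus_purpuratus	0	1	1	1	4	0	1	1	1	2	1	2	1	1	2	1
Acanthaster_planci_OKI	0	1	1	1	2	0	0	0	1	1	1	1	2	1	0	1
Acanthaster_planci_GBR	0	1	1	1	2	0	0	1	1	1	1	1	2	1	1	1
Branchiostoma_belcheri	6	19	1	2	3	2	1	1	1	1	1	1	1	2	2	1
Branchiostoma_floridae	6	5	1	2	1	1	2	1	1	1	1	1	1	3	1	1
Oikopleura_dioica	3	12	5	4	6	2	3	1	4	1	1	3	1	1	1	1
Botryllus_schlosseri	2	1	1	2	3	2	1	2	0	3	1	1	0	0	0	0
Ciona_savignyi	6	8	3	1	2	2	2	1	1	1	1	1	0	1	1	1
Ciona_intestinalis	5	3	3	1	1	2	1	1	1	1	1	1	0	1	1	1
Gallus_gallus	4	11	4	2	2	2	7	3	2	1	3	1	3	4	1	2
Homo_sapiens	4	10	4	3	3	2	7	4	3	3	3	1	3	4	1	3
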