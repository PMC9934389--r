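pdb_id	paralog	ligand	receptor_chains	ligand_chain	central_helix	mutant
2pqk	Mcl-1	Bim	A	B	auto	FALSE
3pk1	Mcl-1	Bax	A	B	auto	FALSE
2kbw	Mcl-1	Bid	A	B	auto	FALSE
3kj0	Mcl-1	Bim_I2dY	A	B	auto	TRUE
3kj2	Mcl-1	Bim_F4aE	A	B	auto	TRUE
3mqp	BFL-1_A1	Noxa	A	B	auto	FALSE
2voi	BFL-1_A1	Bid	A	B	auto	FALSE
2vm6	BFL-1_A1	Bim	A	B	auto	FALSE
2voh	BFL-1_A1	Bak	A	B	auto	FALSE
2vog	Murine_BFL-1	BMF	A	B	auto	FALSE
2vof	Murine_BFL-1	Puma	A	B	auto	FALSE
2wh6	BHRF1	Bim	A	B	auto	FALSE
2xpx	BHRF1	Bak	A	B	auto	FALSE
3fdl	BCL-xL	Bim	A	B	auto	FALSE
1bxl	BCL-xL	Bak	A	B	auto	FALSE
1g5j	BCL-xL	Bad	A	B	auto	FALSE
3io8	BCL-xL	Bim_L12F	A	B	auto	TRUE
2pon	BCL-xL	Beclin-1	A	B	auto	FALSE
2xa0	BCL-2	Bax	A	B	auto	FALSE
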