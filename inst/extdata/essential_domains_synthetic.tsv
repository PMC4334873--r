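# Synthetic stand-in panel of 102 universal prokaryotic Pfam-A domains.
# The published 102-entry panel is distributed only as supplementary
# material; this file is a synthetic reconstruction drawn from Pfam-A
# families of the core translation, transcription and replication
# machinery that are near-universal in finished bacterial and archaeal
# genomes. Replace it with any accession list via scoring_config().
# Columns: accession <TAB> family
PF00687	Ribosomal_L1
PF00181	Ribosomal_L2
PF03947	Ribosomal_L2_C
PF00297	Ribosomal_L3
PF00573	Ribosomal_L4
PF00281	Ribosomal_L5
PF00673	Ribosomal_L5_C
PF00347	Ribosomal_L6
PF03948	Ribosomal_L9_C
PF01281	Ribosomal_L9_N
PF00466	Ribosomal_L10
PF00298	Ribosomal_L11
PF03946	Ribosomal_L11_N
PF00542	Ribosomal_L12
PF00572	Ribosomal_L13
PF00238	Ribosomal_L14
PF00828	Ribosomal_L27A
PF00252	Ribosomal_L16
PF01196	Ribosomal_L17
PF00861	Ribosomal_L18p
PF01245	Ribosomal_L19
PF00453	Ribosomal_L20
PF00829	Ribosomal_L21p
PF00237	Ribosomal_L22
PF00276	Ribosomal_L23
PF17136	Ribosomal_L24
PF00467	KOW
PF00831	Ribosomal_L29
PF00327	Ribosomal_L30
PF00471	Ribosomal_L33
PF00468	Ribosomal_L34
PF01632	Ribosomal_L35p
PF00444	Ribosomal_L36
PF00318	Ribosomal_S2
PF00189	Ribosomal_S3_C
PF07650	KH_2
PF00163	Ribosomal_S4
PF01479	S4
PF00333	Ribosomal_S5
PF03719	Ribosomal_S5_C
PF01250	Ribosomal_S6
PF00177	Ribosomal_S7
PF00410	Ribosomal_S8
PF00380	Ribosomal_S9
PF00338	Ribosomal_S10
PF00411	Ribosomal_S11
PF00164	Ribosom_S12_S23
PF00416	Ribosomal_S13
PF00253	Ribosomal_S14
PF00312	Ribosomal_S15
PF00886	Ribosomal_S16
PF00366	Ribosomal_S17
PF01084	Ribosomal_S18
PF00203	Ribosomal_S19
PF01649	Ribosomal_S20p
PF00009	GTP_EFTU
PF03144	GTP_EFTU_D2
PF03143	GTP_EFTU_D3
PF00889	EF_TS
PF00679	EFG_C
PF14492	EFG_II
PF03764	EFG_IV
PF01926	MMR_HSR1
PF11987	IF-2
PF04760	IF2_N
PF01176	eIF-1a
PF00707	IF3_C
PF05198	IF3_N
PF01765	RRF
PF00472	RF-1
PF00133	tRNA-synt_1
PF00579	tRNA-synt_1b
PF00749	tRNA-synt_1c
PF01409	tRNA-synt_2d
PF00152	tRNA-synt_2
PF00587	tRNA-synt_2b
PF01411	tRNA-synt_2c
PF02912	Phe_tRNA-synt_N
PF00458	HGTP_anticodon
PF01336	tRNA_anti-codon
PF04997	RNA_pol_Rpb1_1
PF00623	RNA_pol_Rpb1_2
PF04983	RNA_pol_Rpb1_3
PF05000	RNA_pol_Rpb1_4
PF04998	RNA_pol_Rpb1_5
PF00562	RNA_pol_Rpb2_6
PF04563	RNA_pol_Rpb2_1
PF04561	RNA_pol_Rpb2_2
PF04565	RNA_pol_Rpb2_3
PF10385	RNA_pol_Rpb2_45
PF00585	RNA_pol_Rpb2_7
PF01000	RNA_pol_A_bac
PF01193	RNA_pol_L
PF01192	RNA_pol_Rpb6
PF00448	SRP54
PF02881	SRP54_N
PF00344	SecY
PF00584	SecE
PF00012	HSP70
PF01025	GrpE
PF00204	DNA_gyraseB
PF00521	DNA_topoisoIV
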