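pdb_id	gene	protein	ratio_099
3CCW	HMDH	HMG-CoA reductase	12353
1XL2	HIVPR	Human immunodeficiency virus type 1 protease	4552
2AYW	TRY1	Trypsin I	1084
1B9V	NRAM	Neuraminidase	816.3
1ZW5	FPPS	Farnesyl diphosphate synthase	803.9
3LQ8	MET	Hepatocyte growth factor receptor	697.1
2ZEC	TRYB1	Tryptase beta-1	405
2V3F	GLCM	Beta-glucocerebrosidase	324
1SYN	TYSY	Thymidylate synthase	137.6
3G6Z	RENI	Renin	98.2
3KL6	FA10	Coagulation factor X	80.4
1LI4	SAHH	Adenosylhomocysteinase	79.3
3BKL	ACE	Angiotensin-converting enzyme	71
3E37	FNTA	Protein farnesyltransferase alpha subunit	68.4737
1SQT	UROK	Urokinase-type plasminogen activator	67.619
1NJS	PUR2	GAR transformylase	48.9796
1LRU	DEF	Peptide deformylase	46.6341
3F9M	HXK4	Hexokinase type IV	43.4
3EQH	MP2K1	Dual specificity MAP kinase kinase 1	40.5
2E1W	ADA	Adenosine deaminase	35.0972
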