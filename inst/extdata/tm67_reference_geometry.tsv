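receptor	structure	pdb_id	resolution	pair	donor_res	acceptor_res	facing	da_distance	cb_d_a_angle	hbond_printed
beta2-adrenergic	b2AR-INV	2RH1	2.4	6.47-7.45	CYS	ASN	CO	3.8	84.5	TRUE
beta2-adrenergic	b2AR-AGO	3SN6	3.2	6.47-7.45	CYS	ASN	CO	4.4	81.2	FALSE
beta1-adrenergic	b1AR-INV	2VT4	2.7	6.47-7.45	CYS	ASN	CO	3.7	79.3	TRUE
beta1-adrenergic	b1AR-AGO	2Y02	2.6	6.47-7.45	CYS	ASN	CO	3.9	85.3	TRUE
dopamine-D3	D3R-INV	3PBL	2.9	6.47-7.45	CYS	ASN	CO	3.8	81.6	TRUE
histamine-H1	H1R-INV	3RZE	3.1	6.47-7.45	CYS	ASN	CO	4.2	80.9	TRUE
adenosine-A2A	A2AR-INV	4EIY	1.8	6.47-7.45	CYS	ASN	NH2	3.9	84.5	TRUE
adenosine-A2A	A2AR-AGO	2YDV	2.6	6.47-7.45	CYS	ASN	CO	4.3	74.4	TRUE
kappa-opioid	kOR-INV	4DJH	2.9	6.47-7.45	CYS	ASN	CO	4.1	81.2	TRUE
mu-opioid	muOR-INV	4DKL	2.8	6.47-7.45	CYS	ASN	CO	3.6	87.5	TRUE
delta-opioid	dOR-INV	4EJ4	3.4	6.47-7.45	CYS	ASN	NH2	3.8	89.8	TRUE
NOFQ-opioid	NOFQ-INV	4EA3	3.0	6.47-7.45	CYS	ASN	NH2	4.2	85.6	TRUE
S1P1	S1PR1-INV	3V2Y	2.8	6.47-7.45	CYS	ASN	NH2	3.4	81.1	TRUE
CXCR4-chemokine	CXCR4-INV	3ODU	2.5	6.47-7.45	CYS	HIS	-	NA	NA	FALSE
M2-muscarinic	M2R-INV	3UON	3.0	6.47-7.45	THR	ASN	NH2	3.2	120.2	TRUE
M3-muscarinic	M3R-INV	4DAJ	3.4	6.47-7.45	THR	ASN	NH2	4.0	140.7	TRUE
rhodopsin-bovine	bRho-INV	1GZM	2.7	6.47-7.44	CYS	THR	-	3.7	101.8	TRUE
rhodopsin-bovine	bRho-AGO	3PQR	2.9	6.47-7.44	CYS	THR	-	8.8	NA	FALSE
rhodopsin-squid	sRho-INV	2Z73	2.5	6.43-7.54	GLN	SER	-	2.4	111.2	TRUE
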