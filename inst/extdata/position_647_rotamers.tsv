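receptor	pdb_id	res_647	rotamer_647	res_744	rotamer_744	res_745
beta2-adrenergic	2RH1	C	g+	V	NA	N
beta1-adrenergic	2VT4	C	g+	V	NA	N
dopamine-D3	3PBL	C	g+	V	NA	N
histamine-H1	3RZE	C	g+	I	NA	N
adenosine-A2A	4EIY	C	g+	T	g+/t	N
kappa-opioid	4DJH	C	g+	T	NA	N
mu-opioid	4DKL	C	g+	T	NA	N
delta-opioid	4EJ4	C	g+	A	NA	N
NOFQ-opioid	4EA3	C	g+	V	NA	N
S1P1	3V2Y	C	g+	L	NA	N
CXCR4-chemokine	3ODU	C	g+	F	NA	H
M2-muscarinic	3UON	T	g-	I	NA	N
M3-muscarinic	4DAJ	T	g-	I	NA	N
rhodopsin-bovine	1GZM	C	t	T	g+/t	S
rhodopsin-squid	2Z73	S	g+	A	NA	S
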