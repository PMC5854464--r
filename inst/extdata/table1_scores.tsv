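step	subline	class	count
F3	S1	mCe	46
F3	S1	mCe+mO+mC	50
F3	S2	mCe	44
F3	S2	mCe+mO+mC	40
F3	S3	mCe	49
F3	S3	mCe+mO+mC	40
F3	S4	mCe	41
F3	S4	mCe+mO+mC	52
F3	S5	mCe	39
F3	S5	mCe+mO+mC	43
F3	S6	mCe	27
F3	S6	mCe+mO+mC	29
F4	S1		30
F4	S1	mCe	40
F4	S1	mO	5
F4	S1	mC	12
F4	S1	mCe+mO	7
F4	S1	mCe+mC	23
F4	S2		36
F4	S2	mCe	38
F4	S2	mO	20
F4	S2	mC	11
F4	S2	mCe+mO	13
F4	S2	mCe+mC	14
F4	S3		33
F4	S3	mCe	42
F4	S3	mO	17
F4	S3	mC	13
F4	S3	mCe+mO	7
F4	S3	mCe+mC	16
F4	S4		14
F4	S4	mCe	15
F4	S4	mO	20
F4	S4	mC	13
F4	S4	mCe+mO	22
F4	S4	mCe+mC	9
F4	S4	mO+mC	3
F4	S4	mCe+mO+mC	4
F4	S5		20
F4	S5	mCe	47
F4	S5	mO	19
F4	S5	mC	10
F4	S5	mCe+mO	12
F4	S5	mCe+mC	9
F4	S6		39
F4	S6	mCe	39
F4	S6	mO	10
F4	S6	mC	8
F4	S6	mCe+mO	7
F4	S6	mCe+mC	13
F5	S1		31
F5	S1	mO	30
F5	S1	mC	27
F5	S1	mO+mC	26
F5	S2		26
F5	S2	mO	30
F5	S2	mC	16
F5	S2	mO+mC	18
F5	S3		30
F5	S3	mO	33
F5	S3	mC	30
F5	S3	mO+mC	28
F5	S4		21
F5	S4	mO	25
F5	S4	mC	41
F5	S4	mO+mC	22
F5	S5		31
F5	S5	mO	32
F5	S5	mC	14
F5	S5	mO+mC	33
F5	S6		22
F5	S6	mO	25
F5	S6	mC	14
F5	S6	mO+mC	23
F6-S	S1	mO	39
F6-S	S1	mC	45
F6-S	S2	mO	49
F6-S	S2	mC	49
F6-S	S3	mO	68
F6-S	S3	mC	58
F6-S	S4	mO	50
F6-S	S4	mC	43
F6-S	S5	mO	59
F6-S	S5	mC	56
F6-S	S6	mO	49
F6-S	S6	mC	37
F6	S1	mO	23
F6	S1	mC	28
F6	S1	mO+mC	62
F6	S2	mO	23
F6	S2	mC	38
F6	S2	mO+mC	46
F6	S3	mO	27
F6	S3	mC	27
F6	S3	mO+mC	64
F6	S4	mO	29
F6	S4	mC	30
F6	S4	mO+mC	73
F6	S5	mO	18
F6	S5	mC	32
F6	S5	mO+mC	53
F6	S6	mO	22
F6	S6	mC	27
F6	S6	mO+mC	62
F7-O	S1	mO	94
F7-O	S2	mO	50
F7-O	S3	mO	49
F7-O	S4	mO	79
F7-O	S5	mO	79
F7-O	S6	mO	63
F7-C	S1	mC	101
F7-C	S2	mC	105
F7-C	S3	mC	89
F7-C	S4	mC	54
F7-C	S5	mC	74
F7-C	S6	mC	64
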