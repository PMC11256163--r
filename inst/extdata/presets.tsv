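name	position	wt	new	rung
alpha-SC3	229	K	Q	1
alpha-SC3	230	D	V	1
alpha-SC3	232	R	N	1
alpha-SC3	234	E	G	1
alpha-SC3	235	E	G	1
alpha-SC3	265	E	Q	2
alpha-SC3	266	T	V	2
alpha-SC3	268	V	N	2
alpha-SC3	269	K	G	2
alpha-SC6	232	R	K	1
alpha-SC6	234	E	V	1
alpha-SC6	236	R	G	1
alpha-SC6	268	V	K	2
alpha-SC6	270	K	V	2
alpha-SC6	271	G	E	2
alpha-SC6	272	E	G	2
alpha-SC8	225	R	K	1
alpha-SC8	227	S	Q	1
alpha-SC8	229	K	T	1
alpha-SC8	261	T	K	2
alpha-SC8	263	S	Q	2
alpha-SC8	265	E	T	2
alpha-SC9	227	S	K	1
alpha-SC9	229	K	V	1
alpha-SC9	230	D	E	1
alpha-SC9	232	R	A	1
alpha-SC9	263	S	K	2
alpha-SC9	265	E	V	2
alpha-SC9	266	T	E	2
alpha-SC9	268	V	A	2
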