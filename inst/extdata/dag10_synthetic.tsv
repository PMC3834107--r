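source	target	weight
N6	N4	0.84
N6	N7	-0.62
N6	N2	0.45
N1	N2	-0.77
N1	N5	0.58
N1	N4	0.36
N4	N7	0.71
N4	N9	-0.41
N4	N2	0.53
N7	N9	0.66
N7	N8	-0.49
N2	N8	0.74
N2	N10	-0.35
N5	N10	0.81
N5	N9	-0.57
N5	N3	0.43
N9	N10	0.62
N9	N3	-0.72
N8	N3	0.55
N8	N10	-0.44
N10	N3	0.68
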