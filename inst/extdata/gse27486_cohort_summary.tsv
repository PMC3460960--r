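variable	group	n	mean	sd
age	case	22	70.6	7.7
age	control	23	59.9	9.1
wbc	case	22	6.7	1.8
wbc	control	17	7.7	2.7
platelets	case	22	233.9	81.1
platelets	control	17	263.4	68.8
hemoglobin	case	22	13.5	1.4
hemoglobin	control	17	13.5	1.3
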