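assay	forward	reverse	amplicon_length	efficiency
muc5ac.1	gacctgctctgtggaaggag	agcacggtgaattcagttcc	120	1.9
muc5ac.2_4	ttttctcagttgccgctttt	agtcggagcccataagaggt	92	1.8
muc5b	attaagagcgatgtcttcacagc	aagcacatgagtctctcacacaa	85	1.9
muc2.1_2	gagtgggctctcagatccag	gatgatgcggacggtagttt	99	1.9
elf1a	caccaccggccatctgatctacaa	tcagcagcctccttctcgaacttc	78	1.9
etif3	caggatgttgttgctggatggg	acccaactgggcaggtcaaga	102	1.9
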