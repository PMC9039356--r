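name	sequence	role	tier	target
WWP1	CGTCTCCAGTCTCCATGTGTTCGTC	WWP	1	NA
WWP2	CGTCTCCAGTCTTAGGCACAGTGTC	WWP	2	NA
WWP3	CGTCTCCAGTCTAGTCAGTCAGGTC	WWP	3	NA
gadAGSP1	TCCATACCCTCATCTCCATTTCCAT	GSP	1	gadA
gadAGSP2	AACTATCACCCCACAACGTCATCTC	GSP	2	gadA
gadAGSP3	ACCGTTCATAGGCGAAATTGTTTGT	GSP	3	gadA
hygGSP1	CGGCAATTTCGATGATGCAGCTTGG	GSP	1	hyg
hygGSP2	CGGGACTGTCGGGCGTACACAAATC	GSP	2	hyg
hygGSP3	GACCGATGGCTGTGTAGAAGTACTC	GSP	3	hyg
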