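library	measure	total	miRNA	rRNA	snRNA	snoRNA	tRNA	unannotated
PF2U	unique	5392667	18131	44693	1637	694	9468	5318044
PF2U	total	16961959	2887692	579878	3064	1526	567569	12922230
PF2S	unique	5605552	18323	68536	2931	911	15976	5498875
PF2S	total	17685354	3204222	746684	7091	1823	593895	13131639
PF4U	unique	5190025	19183	44498	2018	741	8246	5115339
PF4U	total	15021455	2371366	455343	4551	1754	327426	11861015
PF4S	unique	5998800	20816	65837	3572	1062	9985	5897528
PF4S	total	18729181	2614487	913448	9899	2259	623069	14566019
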