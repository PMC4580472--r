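category	total_a	unique_a	total_b	unique_b
Raw reads	38092056	9311258	32969156	7713621
3ADT&length filter	19081207	5670799	17749062	4952497
Junk reads	205372	61494	213241	52070
Rfam	2203115	284387	1623385	246854
Repeats	106331	93061	84599	74144
Clean reads	16527710	3230369	13324372	2411293
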