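class	total_a	unique_a	total_b	unique_b
rRNA	1617108	135768	1197675	123465
tRNA	70911	23706	58754	24125
snoRNA	42572	30220	31274	23939
snRNA	59056	23287	46852	18316
otherRfam	413468	71406	288830	57009
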