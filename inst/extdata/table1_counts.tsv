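family	total	from_wgs	complete	partials	fragments	species_total
WASP	400	375	316	33	50	316
WAVE	344	332	312	9	21	169
WASH	165	148	138	9	17	158
WHAMM	76	68	47	7	22	42
WAWH	19	17	18	0	1	11
WAML	17	17	17	0	0	3
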