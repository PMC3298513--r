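key	value
total_sequences	1021
total_organisms	408
wh2_domain_sequences	1080
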