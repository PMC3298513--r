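logo	n
WASP-WH2A	343
WASP-WH2B	110
WAVE	321
WASH	141
WHAMM-WH2A	63
WHAMM-WH2B	69
WAML	14
WAWH	19
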