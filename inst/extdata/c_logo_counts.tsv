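logo	n
WASP	349
WAVE	321
WASH	154
WHAMM	69
WAML	14
WAWH	19
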