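cold
cool
neutral
warm
hot
sour
bitter
sweet
spicy
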