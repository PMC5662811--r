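lungs
large intestine
stomach
spleen
heart
small intestine
bladder
kidneys
pericardium
triple burner
gallbladder
liver
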