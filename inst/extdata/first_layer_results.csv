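"id","label","score","weight"
"SCI","Scientific nature",9.07,0.341
"RLV","Relevance",8.76,0.338
"CRD","Coordination",8.92,0.321
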