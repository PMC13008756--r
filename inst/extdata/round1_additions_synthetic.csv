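"id","label","definition","layer","parent_id"
"SCI2.4","The standards and regulations in the NFSSF realize risk-based classified and hierarchical management","",3,"SCI2"
"RLV3.3","The NFSSF provides guidance for market regulators to improve their capacities","",3,"RLV3"
"RLV2.4","The NFSSF helps control safety risk at a reasonable cost","",3,"RLV2"
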