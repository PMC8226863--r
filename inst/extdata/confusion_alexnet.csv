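"","QRS_WIDENING","SINUS_RHYTHM","ST_DEPRESSION","ST_ELEVATION"
"QRS_WIDENING",2754,56,95,44
"SINUS_RHYTHM",64,2855,26,4
"ST_DEPRESSION",43,44,2857,5
"ST_ELEVATION",76,6,21,2846
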