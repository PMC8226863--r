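"","QRS_WIDENING","SINUS_RHYTHM","ST_DEPRESSION","ST_ELEVATION"
"QRS_WIDENING",2187,128,276,358
"SINUS_RHYTHM",626,2122,86,115
"ST_DEPRESSION",311,183,2034,421
"ST_ELEVATION",197,75,126,2551
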