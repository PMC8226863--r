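"","QRS_WIDENING","SINUS_RHYTHM","ST_DEPRESSION","ST_ELEVATION"
"QRS_WIDENING",2803,30,47,69
"SINUS_RHYTHM",39,2904,3,3
"ST_DEPRESSION",54,61,2827,7
"ST_ELEVATION",29,6,5,2909
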