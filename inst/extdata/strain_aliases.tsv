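alias	canonical
12-1 ( = CCMP371)	12-1
12-1 ( = CCMP371) (Sargasso Sea)	12-1
CCMP371	12-1
CCMP379 ( = 92A, according to CCMP)	CCMP379
CCMP379 (Unknown)	CCMP379
Van556	Van 556
CH24/90	CH 24/90
CH25/90	CH 25/90
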