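strain	coccoliths	collection_site	isolation_date
92	N	English Channel	1950
92A	N	English Channel	1957
92D	Y	English Channel	1975
92E	Y	English Channel	1992
92F	Y	English Channel	1992
CCMP379	N	English Channel	1992
CCMP374	N	Gulf of Maine	1989
CCMP373	N	Sargasso Sea	1960
12-1	Y	Sargasso Sea	1987
CCMP1516	Y	South Pacific	1991
Van 556	N	North Pacific	1984
CH 24/90	Y	North Atlantic	1990
CH 25/90	Y	North Atlantic	1990
L	N	Oslo Fjord	1959
NZEH	Y	South Pacific	1992
EH2	Y	South Pacific	1990
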