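# localized release footprint: 38 cells (950 m^2), col row pairs
18 18
18 19
18 20
18 21
18 22
18 23
19 18
19 19
19 20
19 21
19 22
19 23
20 18
20 19
20 20
20 21
20 22
20 23
21 18
21 19
21 20
21 21
21 22
21 23
22 18
22 19
22 20
22 21
22 22
22 23
23 18
23 19
23 20
23 21
23 22
23 23
24 18
24 19
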