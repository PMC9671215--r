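# Synthetic piecewise-linear binodal for the water/methanol/chloroform
# (Bligh-Dyer) ternary diagram, weight percent, ordered from the water-rich
# end to the chloroform-rich end. Constructed to pass through the commonly
# cited critical composition (ca. 30/15/55 w/w water/methanol/chloroform);
# replace with a digitized experimental curve for quantitative work.
w_water,w_methanol,w_chloroform
98,0,2
92,5,3
85,10,5
70,22,8
55,32,13
42,36,22
32,36,32
26,32,42
30,15,55
18,8,74
8,3,89
2,0,98
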