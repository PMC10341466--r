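# Scenario preset 1: costly supervision (condition A), settles at (0,0,0)
Ch1: 8
Ch2: 5
Ct1: 2
Ct2: 1
Cg: 9
Ih1: 9
Ih2: 10
It1: 3
It2: 4
Ig1: 8
Ig2: 5
Ah: 2
Ph: 2
Pt: 1
Ag: 2
Pg: 3
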