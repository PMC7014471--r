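residue	energy
Glu223	4.1
Leu225	-3.9
Ile228	-2.8
Val231	-2.6
Gln237	2.0
Leu241	-0.2
Tyr244	-0.4
Lys372	2.2
Phe760	-3.6
Arg761	1.8
Met763	-1.2
Leu764	-2.9
Phe771	-2.1
Leu781	-2.4
Phe1090	-0.1
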