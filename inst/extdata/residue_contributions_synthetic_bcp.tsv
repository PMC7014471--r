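residue	energy
Glu223	3.4
Leu225	-4.8
Ile228	-3.6
Val231	-3.1
Gln237	1.6
Leu241	-0.4
Tyr244	-0.6
Lys372	1.9
Phe760	-4.2
Arg761	1.3
Met763	-1.7
Leu764	-3.5
Phe771	-2.8
Leu781	-3.0
Phe1090	-0.3
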