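residue	energy
Glu223	16.3
Leu225	-1.8
Ile228	-0.6
Val231	-5.2
Gln237	2.1
Leu241	-4.6
Tyr244	-3.9
Lys372	1.4
Phe760	-6.1
Arg761	2.6
Met763	-0.8
Leu764	-4.3
Phe771	-0.9
Leu781	-0.7
Phe1090	-5.0
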