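protein_a	protein_b
Beat-Ia	Side
Beat-Ib	Side
Beat-IIa	Side-IV
Beat-IIb	Side-IV
Beat-Va	Side-VI
Beat-Vb	Side-VI
Beat-Vc	Side-VI
CG17839	Side-VII
Side-II	Side-III
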