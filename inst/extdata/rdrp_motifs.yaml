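# Curated consensus approximations of the eight conserved RdRp sequence
# motifs (I-VIII) of dsRNA viruses, for use with scan_motifs(). These are
# configuration distilled from the mycovirus RdRp literature, not values
# computed by this package; motif VI carries the classic (S/G)DD
# polymerase core. Syntax: exact residues, [..] alternatives, x wildcard,
# {n,m} repetition.
I: "Kx[QE][RK]"
II: "[ST]x{2}G[DN]"
III: "[DE]x{2}[FY]D"
IV: "Dx{3}[FY]D"
V: "G[LIVM]PSG"
VI: "SG[DN]D"
VII: "[RK]x{2}[LIVM]R"
VIII: "[EQ]F[LIVM]R"
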