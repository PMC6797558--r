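# Synthetic totivirus-like genome architecture (yeast-totivirus layout).
# All coordinates are 1-based inclusive on the plus strand. This is a
# synthetic stand-in: the generator realizes the layout with random
# neutral background, it does not reproduce any deposited sequence.
name: TkTV1-like-synthetic
total_length: 4712
utr5_length: 97
utr3_length: 59
stop_codon: UAA
min_orf_length: 300
orfs:
  - name: ORF1          # coat protein; frame 2; 2064 nt -> 687 aa
    start: 98
    end: 2161
  - name: ORF2          # RdRp; frame 1; 2244 nt -> 747 aa
    start: 2410
    end: 4653
slippery:
  position: 2104        # heptamer 2104-2110, ends 51 nt before the ORF1 stop
  heptamer: UGUUUUC
# 19 nt spacer (2111-2129) between heptamer and pseudoknot; fixed part of
# the planted cassette, U-free so it is stop-free in every reading frame
spacer: CAGCACGACAGCAGGACCA
pseudoknot:             # H-type, 2130-2154 (25 nt): 6 bp stem1 + 5 bp stem2
  start: 2130
  stem1_len: 6
  stem2_len: 5
  loop1_extra: 1
  loop2_len: 2
fusion:
  minus_frame_start: 1990   # -1 frame stop-free from here to the ORF2 stop
                            # -> 172 nt ORF1/ORF2 overlap, 1518 aa fusion
mutations:              # companion-isolate point substitutions
  - {position: 84,   effect: utr}
  - {position: 1003, effect: silent}
  - {position: 1336, effect: silent}
  - {position: 1952, effect: nonsynonymous}
  - {position: 3507, effect: silent}
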