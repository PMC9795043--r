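# Region boundaries for the packaged synthetic germline segments.
# V regions are half-open, 0-based nucleotide intervals; the sequence 3' of
# fr3 is the junction-contributing tail. J fr4_start is the offset of the
# conserved FR4 tryptophan codon within the segment. D frames are the
# reading frames the stereotyped rearrangements use.
IGHV1-S1:
  class: V
  fr1: [0, 75]
  cdr1: [75, 99]
  fr2: [99, 150]
  cdr2: [150, 174]
  fr3: [174, 249]
IGHD6-19S:
  class: D
  frames: [1]
IGHJ4S:
  class: J
  fr4_start: 9
IGHV1-69S:
  class: V
  fr1: [0, 75]
  cdr1: [75, 99]
  fr2: [99, 150]
  cdr2: [150, 174]
  fr3: [174, 249]
IGHD3-16S:
  class: D
  frames: [2]
IGHJ3S:
  class: J
  fr4_start: 12
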