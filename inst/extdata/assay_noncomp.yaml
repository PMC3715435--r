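# Interchromosomal translocation assay with completely non-complementary
# 4-nt 3' overhangs: the I-SceI cleavage site in inverse orientation, so the
# junction-facing I-SceI end presents the other half of the recognition
# sequence (overhang TTAT) while the HO end is unchanged (overhang TGTT).
# TTAT and TGTT cannot anneal at their tips in any register.
#
# SYNTHETIC / TRANSCRIBED-UNVERIFIED: flanking context reconstructed, see
# assay_partial.yaml.
name: noncomp
system: noncomp
overhang_length: 4
left_end:
  # inverted I-SceI end: duplex_top ends with ATTACCCTG + overhang TTAT
  duplex_top: CTGCAGGTCGACTCTAGAGGATCCCGATTACCCTGTTAT
  overhang: TTAT
right_end:
  duplex_top: GTATAATAACGGTTCGCTGCCTGGCCTTGTCTCCGGTGAGCCTG
  overhang: TGTT
left_anchor: CTGCAGGTCGAC
right_anchor: CCGGTGAGCCTG
max_deletion: 25
max_insertion: 6
karyotype:
  # figure-legend sizes are rounded to the kb; XV is entered as 1090 kb here
  # so that material is conserved exactly (1450 + 730 = 1090 + 1090)
  chromosomes:
    - {name: VII, length_kb: 1090, break_kb: 1055}
    - {name: XV, length_kb: 1090, break_kb: 695}
  translocants:
    - {name: tVII/XV, left_of: VII, right_of: XV}
    - {name: tXV/VII, left_of: XV, right_of: VII}
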