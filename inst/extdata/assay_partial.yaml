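# Interchromosomal translocation assay, partially-complementary 4-nt 3'
# overhangs (HO x I-SceI).
#
# SYNTHETIC / TRANSCRIBED-UNVERIFIED: the original junction-flank panels are
# published only as figure images, so the flanking (intron) context below is a
# synthetic reconstruction.  The I-SceI-side overhang (ATAA) follows from the
# published I-SceI recognition sequence; the HO-side overhang (TGTT) and the
# flanks were solved to be consistent with the assay's published repair
# signatures: a templated +CA/+AT fill after 2-nt tip pairing, a 3-nt pairing
# containing a single internal T:G mismatch after trimming one terminal base
# from each protruding strand, and a 4-nt microhomology patch (ATAA) in the
# HO-side flank.
name: partial
system: partial
overhang_length: 4
left_end:
  # I-SceI-cut end; duplex_top ends with the recognition 5' half TAGGGATAA,
  # whose last four bases are the 3' overhang
  duplex_top: CTGCAGGTCGACTCTAGAGGATCCCGTCGGTAGGGATAA
  overhang: ATAA
right_end:
  # HO-cut end; top strand starts at the recessed terminus (GTATA...), the
  # bottom strand protrudes with 3' overhang TGTT (= revcomp of AACA)
  duplex_top: GTATAATAACGGTTCGCTGCCTGGCCTTGTCTCCGGTGAGCCTG
  overhang: TGTT
left_anchor: CTGCAGGTCGAC
right_anchor: CCGGTGAGCCTG
max_deletion: 25
max_insertion: 6
karyotype:
  # fragment lengths in kb; break positions transcribed from the assay
  # scheme (figure-only; unverified against text)
  chromosomes:
    - {name: III, length_kb: 316, break_kb: 200}
    - {name: XV, length_kb: 1091, break_kb: 695}
  translocants:
    - {name: tIII/XV, left_of: III, right_of: XV}
    - {name: tXV/III, left_of: XV, right_of: III}
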