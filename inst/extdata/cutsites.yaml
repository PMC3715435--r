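# Endonuclease cut-site specifications.  Offsets are 0-based on the
# top-strand coordinate system; the 3' overhang is recognition[bottom..top).
# I-SceI: published 18-bp recognition sequence, 4-nt 3' overhang ATAA.
# HO: site context transcribed (figure-only; unverified against text); the
# 4-nt 3' overhang AACA / TGTT matches the assay configurations.
sites:
  - name: I-SceI
    recognition: TAGGGATAACAGGGTAAT
    top_cut: 9
    bottom_cut: 5
  - name: HO
    recognition: TTCAGCTTTCCGCAACAGTATA
    top_cut: 17
    bottom_cut: 13
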