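# Golden Gate linker overhang convention for two-step pegRNA cloning
# (spacer linker first, RTT-PBS extension linker second).
# These 4-nt overhangs are a documented CONVENTION for U6 sgRNA/pegRNA
# acceptor backbones -- always verify against the actual digestion
# products of your own backbone before ordering oligos.
spacer_top_overhang: ACCG
spacer_bottom_overhang: AAAC
extension_top_overhang: GTGC
extension_bottom_overhang: AAAA
spacer_enzyme: BpiI
extension_enzyme: BsmBI
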