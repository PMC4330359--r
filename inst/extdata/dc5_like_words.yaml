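# Default composite sox-pax word set for DC5-like genome scanning.
# This is a reconstructed package default: the sox half-site is the canonical
# Sox consensus and the pax half-site is a degenerate DC5-style word. It is
# NOT a published word list; supply your own words for production scans.
sox_word: CATTGT
gap: 0
pax_word: TGTTGY
pax_orientation: forward
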