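>PAX6LIKE_SYNTH synthetic Pax6-like PFM (constructed stand-in, not a JASPAR download)
A [ 23 23  2 31 23 23 31  2  2 23  2 31 23 23 ]
C [ 23 31  2 23 23 31 23  2 94 23  2 23 23 23 ]
G [ 31 23  2 23 23 23 23 94  2 23  2 23 31 23 ]
T [ 23 23 94 23 31 23 23  2  2 31 94 23 23 31 ]
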