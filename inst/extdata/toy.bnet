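# Three-component demonstration network.
# Mutual inhibition between g1 and g2; g1 activates g3; g3 activates g2
# and sustains itself.  Five signed interactions in total.
# Fixed points of the asynchronous dynamics: 101 and 011.
targets, factors
g1, !g2
g2, !g1 & g3
g3, g1 | g3
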