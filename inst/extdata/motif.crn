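# The two-reaction dual-rail conversion motif.
# Input signal X (rails X_hi/X_lo) copies its Boolean value onto output Y.
init X_hi 10
init X_lo 0
init Y_hi 0
init Y_lo 10
X_hi + Y_lo ->{1} X_hi + Y_hi
X_lo + Y_hi ->{1} X_lo + Y_lo
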