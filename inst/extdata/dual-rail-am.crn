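# Dual-rail Approximate Majority circuit: inputs X, Y, output Z, undecided
# intermediary lambda.  Initial condition: both inputs low, output committed
# high -- the inputs win and the output flips low within about 0.5 s.
init X_hi 0
init X_lo 10
init Y_hi 0
init Y_lo 10
init Z_hi 10
init Z_lo 0
init lambda 0
X_hi + Z_lo ->{1} X_hi + lambda
Z_hi + Z_lo ->{1} Z_hi + lambda
X_lo + Z_hi ->{1} X_lo + lambda
Z_lo + Z_hi ->{1} Z_lo + lambda
Y_hi + lambda ->{1} Y_hi + Z_hi
Z_hi + lambda ->{1} Z_hi + Z_hi
Y_lo + lambda ->{1} Y_lo + Z_lo
Z_lo + lambda ->{1} Z_lo + Z_lo
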