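# Forced refinement outputs on the rbw_example instance, with the
# coloring R = {R1,R2}, B = {B1,B2}, W = {W1,W2,W3} taken at the node
# above the red and blue groups in T1.  Components are written one per
# line, labels space-separated.

[make_rb_compatible from {all labels}]
B1 R1
B2 R2 W1 W2 W3

[make_splittable from {R1} {B1 B2 W1 R2 W2} {W3}; cut at lca2(B2,W1)]
R1
B2 W1
B1 R2 W2
W3

[split from {R1} {B2 W1} {B1 R2 W2} {W3}]
B1
B2
R1
R2
W1
W2
W3

[split from {B1 R1} {B2 W1 R2 W2 W3}; four-way special split at lca2(B2,R2)]
B1
B2
R1
R2
W1 W2
W3
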