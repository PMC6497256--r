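# Four-node worked example driven by a single control input u:
# u = 1 forces (v1, v2) to (1, 0); u = 0 exchanges v1 and v2.
external: u
targets, factors
v1, u | (!u & v2)
v2, !u & v1
v3, v1
v4, v2 & v3
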