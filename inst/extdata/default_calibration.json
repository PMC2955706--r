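{"mu_max":0.219110378912685,"K":112.901812191104,"par_compensation":0.2}
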