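root R
edge Baka_t R Baka 0.015
edge ooa R OOA 0.01
edge west OOA W1 0.004
edge east OOA E1 0.006
edge French_t W1 French 0.005
edge y W1 W2 0.002
edge Han_t E1 Han 0.006
edge x E1 E2 0.0025
edge z pAM Mixe 0.0075
admix pAM E2 W2 0.7
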