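root R
edge Baka_t R Baka
edge ooa R OOA
edge west OOA W1
edge east OOA E1
edge French_t W1 French
edge y W1 W2
edge Han_t E1 Han
edge x E1 E2
edge z pAM Mixe
admix pAM E2 W2
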