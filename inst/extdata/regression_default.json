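{"intercept":9.62082130829516,"slope":-2.15476472897727,"residual_sd":1.01627369970309,"n_train":500,"mean_ln_x":4.46459022891446,"sxx":72.3599115389614,"clcr_min":25,"clcr_max":255}
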