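cohort	n_censored	n_uncensored
blca	223	173
kirc	209	102
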