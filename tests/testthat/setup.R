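# the benchmark blocks intentionally report every unmet quantitative check;
# do not let the progress reporter abort the remaining files
options(testthat.progress.max_fails = 1000)
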