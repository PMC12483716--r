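# Report every failure: the end-to-end study checks assert many orderings
# and must not cut the run short for the remaining contexts.
options(testthat.progress.max_fails = 1000L)
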