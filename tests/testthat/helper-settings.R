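# Report every failure rather than aborting the run at testthat's default
# cap: the acceptance checks deliberately include read-level-test
# comparisons that are expected to miss their band, and the remaining
# files must still run.
options(testthat.progress.max_fails = Inf)
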