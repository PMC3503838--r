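# The quantitative-reproduction suite intentionally reports every
# discrepancy from the published values; do not stop the run early because
# of them.
options(testthat.progress.max_fails = 1000)
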