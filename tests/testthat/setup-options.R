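# Several acceptance expectations document known model-level discrepancies
# and are expected to fail; keep the runner from stopping early so every
# file still executes.
options(testthat.progress.max_fails = 100)
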