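# small protocol configuration used by fast protocol-level tests: two slow
# areas dominate the runtime, so epochs are kept short but still >= 10x the
# slowest membrane time constant
small_protocol_config <- function(...) {
  protocol_config(n_iterations = 2, iteration_duration = 1200,
                  pretrain_ms = 60, n_surrogates = 50, ...)
}

# cache expensive shared runs across test files within one session
.avol_test_cache <- new.env(parent = emptyenv())
cached <- function(key, expr) {
  if (!exists(key, envir = .avol_test_cache))
    assign(key, expr, envir = .avol_test_cache)
  get(key, envir = .avol_test_cache)
}
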