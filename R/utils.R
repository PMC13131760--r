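# shared internal helpers

# round half away from zero; base round() is round-half-even and the
# audiometric convention is ordinary rounding
round_half_up <- function(x) sign(x) * floor(abs(x) + 0.5)

# run code under a temporary seed without disturbing the caller's RNG stream;
# seed = NULL means "use the current stream" so nested calls compose under a
# single outer seed
with_seed_or_stream <- function(seed, code) {
  if (is.null(seed)) code else withr::with_seed(as.integer(seed), code)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_qvcv <- function(...) stop(..., call. = FALSE)
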