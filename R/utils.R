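# internal helpers shared across modules

# round-half-up; base round() is round-half-even which is wrong for
# quantizing gray levels (162.5 must become 163, not 162)
round_half_up <- function(x) floor(x + 0.5)

clip255 <- function(x) pmin(pmax(x, 0), 255)

is_scalar_number <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
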