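## Seed management: every stochastic operation takes an integer seed and
## leaves the caller's RNG state untouched. Derived seeds are folded into
## 32-bit signed range so any small base seed is safe.

.withSeed <- function(seed, expr) {
    has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
    if (has) old <- get(".Random.seed", envir = globalenv())
    on.exit({
        if (has) assign(".Random.seed", old, envir = globalenv())
        else if (exists(".Random.seed", envir = globalenv(),
                        inherits = FALSE))
            rm(".Random.seed", envir = globalenv())
    })
    set.seed(as.integer(seed))
    expr
}

## deterministic fan-out of a base seed to named sub-streams
.deriveSeed <- function(seed, ...) {
    parts <- c(...)
    h <- as.double(seed) %% 2147483629
    for (p in parts) {
        pv <- if (is.character(p)) sum(utf8ToInt(p) * 31^(seq_along(utf8ToInt(p)) %% 7))
              else as.double(p)
        h <- (h * 48271 + pv) %% 2147483629
    }
    as.integer(h %% 2147483587) + 1L
}
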