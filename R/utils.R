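## Evaluate an expression under a temporary RNG state.  The caller's
## .Random.seed is restored afterwards so scoring/baseline calls do not
## perturb an enclosing simulation stream.
withSeed <- function(seed, expr) {
    has_seed <- exists(".Random.seed", envir = globalenv(),
                       inherits = FALSE)
    if (has_seed)
        old <- get(".Random.seed", envir = globalenv())
    on.exit({
        if (has_seed) assign(".Random.seed", old, envir = globalenv())
        else if (exists(".Random.seed", envir = globalenv(),
                        inherits = FALSE))
            rm(".Random.seed", envir = globalenv())
    })
    set.seed(seed)
    expr
}

## Derived substreams of a master seed, documented in run manifests.  Kept
## well below .Machine$integer.max for any master seed a user would pass.
deriveSeed <- function(seed, stage) {
    offsets <- c(simulate = 1L, score = 2L, shuffle = 3L, evaluate = 4L)
    if (!stage %in% names(offsets)) stop("unknown stage '", stage, "'")
    (as.integer(seed) %% 1000000L) * 1000L + offsets[[stage]]
}
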