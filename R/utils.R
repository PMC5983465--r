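# Internal utilities: reproducible RNG substreams and stable seed hashing.

# Evaluate `expr` under a temporary RNG state seeded with `seed`, restoring
# the caller's .Random.seed afterwards so library functions stay pure.
withSeed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

# Stable 31-bit hash of character labels, used to derive per-stage /
# per-cell seeds from a master seed so that adding scenarios never perturbs
# the RNG stream of existing cells.
hashSeed <- function(master, ...) {
  label <- paste(c(as.character(master), ...), collapse = "|")
  h <- 0
  for (cp in utf8ToInt(label)) h <- (h * 131 + cp) %% 2147483629
  as.integer((h + as.numeric(master)) %% 2147483629 + 1)
}

clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

runifIn <- function(n, interval) stats::runif(n, interval[1], interval[2])
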