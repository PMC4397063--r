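# internal helpers shared across modules

`%||%` <- function(a, b) if (is.null(a)) b else a

# run code with a private RNG stream; restores the caller's .Random.seed
with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)

is_count <- function(x) length(x) == 1L && is.numeric(x) && !is.na(x) &&
  x == as.integer(x)

# percentages are reported to 2 decimals, coverages as integers (display only)
fmt_pct <- function(x) formatC(x, format = "f", digits = 2)
fmt_cov <- function(x) formatC(round(x), format = "d")
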