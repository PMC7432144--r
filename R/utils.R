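# Internal helpers shared across the package.

# Run `expr` under a temporary RNG state seeded with `seed`, restoring the
# caller's RNG afterwards so library calls never perturb user simulations.
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      get(".Random.seed", envir = globalenv())
    else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
          rm(".Random.seed", envir = globalenv())
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    })
    set.seed(seed)
  }
  force(expr)
}

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

check_number <- function(x, name, lower = -Inf, upper = Inf) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    stopf("'%s' must be a single finite number", name)
  if (x < lower || x > upper)
    stopf("'%s' must be in [%s, %s], got %s", name, lower, upper, x)
  invisible(x)
}

# Column order of the experiment table on disk and in memory.
TABLE_INPUTS <- c("ce_conc", "cf_conc", "adding_day", "harvest_day")
TABLE_RESPONSES <- c("dw", "intra", "extra", "total", "portion")
TABLE_COLUMNS <- c(TABLE_INPUTS, "replicate", TABLE_RESPONSES)
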