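# Internal helpers shared across modules.

# Locale-independent lexicographic order (radix is byte-wise, reproducible).
lexOrder <- function(...) order(..., method = "radix")

lexSort <- function(x) sort(x, method = "radix")

# Full-precision numeric formatting for TSV output; %.17g guarantees that
# reading the printed value back yields the identical double.
fmtNum <- function(x) {
  out <- sprintf("%.17g", x)
  out[is.na(x)] <- "NA"
  out
}

# Nearest-rank pooled thresholds for discretization.  With N sorted values:
#   lower threshold = v[floor(lowFraction * N) + 1]
#   upper threshold = v[ceiling((1 - highFraction) * N)]
# so that, for distinct values, exactly floor(lowFraction*N) cells fall
# strictly below the lower threshold and floor(highFraction*N) strictly above
# the upper one; under ties the strict comparisons keep realized fractions at
# or below the targets.
stateThresholds <- function(values, highFraction, lowFraction) {
  v <- values[!is.na(values)]
  if (length(v) == 0L) stop("no non-missing values to threshold")
  if (diff(range(v)) == 0)
    stop("degenerate thresholds: all pooled values are identical; ",
         "no cell can be labelled HIGH or LOW")
  v <- sort(v)
  n <- length(v)
  kl <- min(floor(lowFraction * n) + 1L, n)
  ku <- max(ceiling((1 - highFraction) * n), 1L)
  if (kl > ku) kl <- ku
  c(lower = v[kl], upper = v[ku])
}

# run RNG-dependent code under an explicit seed without leaking global state
withSeed <- function(seed, expr) {
  hadSeed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (hadSeed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (hadSeed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}

checkUniqueIds <- function(ids, what) {
  if (is.null(ids) || any(is.na(ids)) || any(!nzchar(ids)))
    stop(what, " identifiers must be non-empty strings")
  dup <- ids[duplicated(ids)]
  if (length(dup))
    stop("duplicate ", what, " identifier(s): ",
         paste(unique(dup), collapse = ", "))
  invisible(TRUE)
}
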