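#' @keywords internal
"_PACKAGE"

`%||%` <- function(a, b) if (is.null(a)) b else a

## Run `expr` under a fixed RNG state without disturbing the caller's stream.
with_local_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}

## Deterministic per-stage substream seeds derived from one pipeline seed.
## Keeps every derived seed a valid 32-bit integer.
stage_seed <- function(seed, stage) {
  offsets <- c(simulate = 11L, instruments = 23L, assoc = 37L,
               mr_linear = 53L, mr_mvmr = 67L, mr_nonlinear = 79L,
               boot = 97L, report = 113L)
  off <- offsets[[stage]]
  as.integer((as.numeric(seed) * 127L + off) %% 2147483647)
}

stopf <- function(...) stop(sprintf(...), call. = FALSE)
warnf <- function(...) warning(sprintf(...), call. = FALSE)

is_scalar_num <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)

## Two-sided normal p-value; se = 0 handled as a point mass.
normal_p <- function(beta, se) {
  if (se == 0) return(if (beta == 0) 1 else 0)
  2 * stats::pnorm(-abs(beta / se))
}
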