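#' @keywords internal
"_PACKAGE"

# Run code under a temporary RNG state so callers' streams are untouched.
# All randomness in the package funnels through this helper with an
# explicit integer seed (Mersenne-Twister + Inversion, fixed explicitly so
# streams are reproducible across R versions and option settings).
local_seed <- function(seed, code) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed), kind = "Mersenne-Twister", normal.kind = "Inversion")
  force(code)
}

# Numerically stable log-sum-exp and softmax (max-subtraction contract).
logsumexp <- function(x) {
  m <- max(x)
  m + log(sum(exp(x - m)))
}

softmax <- function(x) {
  e <- exp(x - max(x))
  e / sum(e)
}

# Gumbel (type-I extreme value) draws by inverse CDF of uniforms.
rgumbel <- function(n) -log(-log(stats::runif(n)))

`%||%` <- function(a, b) if (is.null(a)) b else a

is_flag <- function(x) is.logical(x) && length(x) == 1L && !is.na(x)

stop_dce <- function(fmt, ..., class = "dcekit_error") {
  stop(errorCondition(sprintf(fmt, ...), class = c(class, "error", "condition")))
}
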