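#' Halton low-discrepancy sequence
#'
#' Deterministic radical-inverse sequence in a prime base, with the first
#' `drop` elements discarded (the leading points of a Halton sequence are
#' strongly patterned, so a burn-in is conventional). Values lie strictly
#' in (0, 1) and are used, via the normal quantile function, to simulate
#' the mixed-logit likelihood integral.
#'
#' @param base prime base.
#' @param n number of points to return.
#' @param drop number of initial points to discard (default 0).
#' @return numeric vector of length `n` in (0, 1).
#' @export
halton_sequence <- function(base, n, drop = 0L) {
  if (!is_prime(base)) stop_dce("Halton base must be prime, got %s", base)
  if (n < 1L) stop_dce("n must be >= 1")
  idx <- seq_len(n + drop)[(drop + 1L):(n + drop)]
  vapply(idx, radical_inverse, numeric(1), base = base)
}

radical_inverse <- function(i, base) {
  f <- 1
  r <- 0
  while (i > 0) {
    f <- f / base
    r <- r + f * (i %% base)
    i <- i %/% base
  }
  r
}

is_prime <- function(x) {
  x <- as.integer(x)
  if (is.na(x) || x < 2L) return(FALSE)
  if (x < 4L) return(TRUE)
  if (x %% 2L == 0L) return(FALSE)
  d <- 3L
  while (d * d <= x) {
    if (x %% d == 0L) return(FALSE)
    d <- d + 2L
  }
  TRUE
}

# First n primes, for assigning one Halton base per random coefficient.
first_primes <- function(n) {
  out <- integer(0)
  x <- 2L
  while (length(out) < n) {
    if (is_prime(x)) out <- c(out, x)
    x <- x + 1L
  }
  out
}

# Standard-normal draw array for MMNL simulation: dims [K, n_draws, n_resp].
# Respondent r uses points (r-1)*D+1 .. r*D of each parameter's sequence,
# parameter k uses the k-th prime as base; the first `drop` points of every
# sequence are discarded. Deterministic by construction.
halton_normal_draws <- function(K, n_draws, n_resp, drop = 10L) {
  bases <- first_primes(K)
  total <- n_draws * n_resp
  z <- array(0, dim = c(K, n_draws, n_resp))
  for (k in seq_len(K)) {
    u <- halton_sequence(bases[k], total, drop = drop)
    # clamp away from 0/1 so qnorm stays finite
    u <- pmin(pmax(u, 1e-12), 1 - 1e-12)
    z[k, , ] <- stats::qnorm(u)
  }
  z
}
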