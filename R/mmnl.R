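# Mixed multinomial logit by maximum simulated likelihood.
#
# Panel structure: each respondent gets one vector of coefficient draws
# spanning all of their tasks. Coefficients are normally distributed,
# beta_r = b + s * z_r, with z_r standard-normal transforms of Halton
# points (one prime base per parameter, first 10 points dropped).

mmnl_workspace <- function(dataset, n_draws, drop = 10L, scramble = FALSE,
                           seed = 1L) {
  ws <- mnl_workspace(dataset)
  resp_ids <- unique(ws$respondent)
  K <- ncol(ws$X)
  z <- halton_normal_draws(K, n_draws, length(resp_ids), drop = drop)
  if (scramble) {
    z <- local_seed(seed, {
      shift <- stats::runif(K)
      u <- stats::pnorm(z)
      u <- (u + array(shift, dim = dim(u))) %% 1
      u <- pmin(pmax(u, 1e-12), 1 - 1e-12)
      stats::qnorm(u)
    })
  }
  # per-respondent slices of the row-sorted design
  row_resp <- ws$respondent
  split_rows <- split(seq_along(row_resp), factor(row_resp, levels = resp_ids))
  list(ws = ws, z = z, n_draws = n_draws, resp_ids = resp_ids,
       split_rows = split_rows, K = K)
}

# Simulated log-likelihood and analytic gradient at theta = c(b, s).
mmnl_simulated_loglik <- function(theta, mws) {
  ws <- mws$ws
  K <- mws$K
  D <- mws$n_draws
  J <- ws$J
  b <- theta[seq_len(K)]
  s <- theta[K + seq_len(K)]
  ll <- 0
  grad <- numeric(2L * K)
  for (r in seq_along(mws$resp_ids)) {
    rows <- mws$split_rows[[r]]
    Xr <- ws$X[rows, , drop = FALSE]
    Tt <- length(rows) %/% J
    zr <- matrix(mws$z[, , r], nrow = K)          # K x D
    B <- b + s * zr                               # K x D coefficient draws
    U <- Xr %*% B                                 # (J*T) x D
    # per-task max subtraction for stability
    A <- array(U, dim = c(J, Tt, D))
    M <- A[1, , , drop = TRUE]
    if (Tt == 1L || D == 1L) M <- matrix(M, Tt, D)
    if (J > 1L) for (j in 2:J) {
      Aj <- A[j, , , drop = TRUE]
      if (Tt == 1L || D == 1L) Aj <- matrix(Aj, Tt, D)
      M <- pmax(M, Aj)
    }
    E <- exp(U - M[rep(seq_len(Tt), each = J), , drop = FALSE])
    S <- rowsum(E, rep(seq_len(Tt), each = J), reorder = FALSE)  # T x D
    P <- E / S[rep(seq_len(Tt), each = J), , drop = FALSE]       # (J*T) x D
    ch <- which(ws$chosen[rows])                  # J*T row indices of chosen
    logL_d <- colSums(log(P[ch, , drop = FALSE]))
    if (Tt == 1L) logL_d <- as.vector(log(P[ch, , drop = FALSE]))
    m0 <- max(logL_d)
    w_raw <- exp(logL_d - m0)
    sum_w <- sum(w_raw)
    ll <- ll + m0 + log(sum_w / D)
    w <- w_raw / sum_w                            # draw weights
    y <- as.numeric(ws$chosen[rows])
    scores <- crossprod(Xr, y - P)                # K x D score per draw
    grad[seq_len(K)] <- grad[seq_len(K)] + as.vector(scores %*% w)
    grad[K + seq_len(K)] <- grad[K + seq_len(K)] +
      as.vector((scores * zr) %*% w)
  }
  structure(ll, gradient = grad)
}

#' Fit a mixed multinomial logit (random-coefficients) model
#'
#' Maximum simulated likelihood with normally distributed random
#' coefficients for all parameters: per respondent the likelihood is the
#' average over draws of the product of that respondent's task-level
#' choice probabilities, with coefficient draws `b + s * z` shared across
#' the respondent's tasks (panel mixing). `z` comes from Halton sequences
#' (successive prime bases per parameter, first `drop` points discarded,
#' no scrambling by default), so the fit is deterministic given `n_draws`
#' and `seed`. The SD parameters enter unrestricted and are reported as
#' `|s|`. With all SDs at zero the simulated likelihood collapses exactly
#' to the multinomial logit likelihood.
#'
#' @param dataset a [choice_dataset()] with repeated tasks per respondent.
#' @param n_draws simulation draws per respondent (the study specification
#'   is 1000).
#' @param seed integer seed, recorded in the result; used for draws only
#'   when `scramble = TRUE`.
#' @param start optional start `c(b, s)`; defaults to the MNL estimates
#'   with SDs 0.1.
#' @param drop initial Halton points discarded per sequence.
#' @param scramble random-shift scrambling of the Halton points.
#' @param max_iter BFGS iteration cap.
#' @param compute_se compute standard errors via a finite-difference
#'   Hessian of the simulated likelihood (adds many gradient evaluations).
#' @return a `dce_fit` with `model = "MMNL"`, mean estimates in
#'   `estimates`, SDs in `sigma` (plus `sigma_se` when requested).
#' @export
fit_mmnl <- function(dataset, n_draws = 1000L, seed = 1L, start = NULL,
                     drop = 10L, scramble = FALSE, max_iter = 200L,
                     compute_se = TRUE) {
  mws <- mmnl_workspace(dataset, n_draws, drop = drop, scramble = scramble,
                        seed = seed)
  tasks_per_resp <- vapply(mws$split_rows, length, integer(1)) / mws$ws$J
  if (all(tasks_per_resp <= 1))
    stop_dce("panel structure required: respondents need multiple tasks")
  K <- mws$K
  if (is.null(start)) {
    mnl <- fit_mnl(dataset)
    start <- c(mnl$estimates, rep(0.1, K))
  }
  fn <- function(th) -as.numeric(mmnl_simulated_loglik(th, mws))
  gr <- function(th) -attr(mmnl_simulated_loglik(th, mws), "gradient")
  opt <- stats::optim(start, fn, gr, method = "BFGS",
                      control = list(maxit = max_iter, reltol = 1e-10))
  theta <- opt$par
  final <- mmnl_simulated_loglik(theta, mws)
  g <- attr(final, "gradient")
  nm <- colnames(mws$ws$X)
  b <- stats::setNames(theta[seq_len(K)], nm)
  s <- stats::setNames(abs(theta[K + seq_len(K)]), nm)
  vc <- NULL
  se <- rep(NA_real_, K)
  sigma_se <- rep(NA_real_, K)
  if (compute_se) {
    H <- numeric_jacobian(function(th) attr(mmnl_simulated_loglik(th, mws),
                                            "gradient"), theta)
    H <- (H + t(H)) / 2
    vc <- tryCatch(solve(-H), error = function(e) NULL)
    if (!is.null(vc)) {
      dv <- diag(vc)
      se <- sqrt(pmax(dv[seq_len(K)], 0))
      sigma_se <- sqrt(pmax(dv[K + seq_len(K)], 0))
      dimnames(vc) <- list(c(nm, paste0("sd.", nm)), c(nm, paste0("sd.", nm)))
    }
  }
  structure(list(
    model = "MMNL",
    estimates = b, sigma = s,
    se = stats::setNames(se, nm), sigma_se = stats::setNames(sigma_se, nm),
    vcov = vc,
    log_likelihood = as.numeric(final),
    gradient = g, gradient_norm = max(abs(g)),
    converged = opt$convergence == 0,
    diverged = FALSE,
    iterations = opt$counts[["function"]],
    n_respondents = length(mws$resp_ids),
    n_tasks = mws$ws$n_tasks, n_obs = nrow(mws$ws$X),
    n_draws = n_draws, seed = seed,
    catalogue = attr(dataset, "catalogue"),
    attributes = attr(dataset, "attributes")
  ), class = "dce_fit")
}

# Central finite-difference Jacobian (used only for MMNL standard errors).
numeric_jacobian <- function(f, x, eps = 1e-5) {
  n <- length(x)
  f0 <- f(x)
  J <- matrix(0, length(f0), n)
  for (i in seq_len(n)) {
    h <- eps * max(1, abs(x[i]))
    xp <- x; xp[i] <- xp[i] + h
    xm <- x; xm[i] <- xm[i] - h
    J[, i] <- (f(xp) - f(xm)) / (2 * h)
  }
  J
}
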