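#' Systematic utility of a coded alternative
#'
#' The deterministic part of random utility: the linear combination of a
#' coded attribute row and a coefficient vector. Columns are matched by
#' name and must align exactly.
#'
#' @param beta named coefficient vector.
#' @param coded_row named numeric vector (one alternative's coded columns).
#' @return scalar utility.
#' @export
systematic_utility <- function(beta, coded_row) {
  if (is.null(names(beta)) || is.null(names(coded_row)))
    stop_dce("beta and coded_row must both be named")
  if (!setequal(names(beta), names(coded_row)))
    stop_dce("coefficient/column mismatch: %s",
             paste(union(setdiff(names(beta), names(coded_row)),
                         setdiff(names(coded_row), names(beta))), collapse = ", "))
  sum(beta * coded_row[names(beta)])
}

#' Multinomial logit choice probabilities for one task
#'
#' Softmax of the systematic utilities over the alternatives of a task,
#' stabilised by subtracting the maximum utility before exponentiating, so
#' probabilities are finite, strictly positive and sum to one for any
#' coefficient values.
#'
#' @param beta named coefficient vector.
#' @param task_rows numeric matrix, one row per alternative, columns
#'   matching `names(beta)`.
#' @return probability vector over the alternatives.
#' @export
choice_probabilities <- function(beta, task_rows) {
  task_rows <- as.matrix(task_rows)
  if (nrow(task_rows) < 2L) stop_dce("a task needs at least 2 alternatives")
  if (!is.null(colnames(task_rows))) {
    if (!setequal(names(beta), colnames(task_rows)))
      stop_dce("coefficient/column mismatch")
    task_rows <- task_rows[, names(beta), drop = FALSE]
  } else if (ncol(task_rows) != length(beta)) {
    stop_dce("coefficient/column mismatch")
  }
  softmax(as.vector(task_rows %*% beta))
}

# Internal fast representation: rows sorted by (respondent, task, alt) with
# a constant number of alternatives J per task.
mnl_workspace <- function(dataset) {
  df <- as.data.frame(dataset)
  ord <- order(df$respondent_id, df$task_id, df$alt_id)
  df <- df[ord, ]
  X <- as.matrix(df[, coded_columns(dataset), drop = FALSE])
  key <- paste(df$respondent_id, df$task_id, sep = "\r")
  J <- as.integer(nrow(df) / length(unique(key)))
  n_tasks <- nrow(df) / J
  list(X = X, chosen = df$chosen == 1, J = J, n_tasks = n_tasks,
       task_of_row = rep(seq_len(n_tasks), each = J),
       respondent = df$respondent_id,
       resp_of_task = df$respondent_id[seq(1L, nrow(df), by = J)])
}

# Probabilities for every row given beta, plus per-task chosen log-prob.
mnl_prob <- function(ws, beta) {
  u <- matrix(ws$X %*% beta, ncol = ws$J, byrow = TRUE)
  u <- u - apply(u, 1L, max)
  e <- exp(u)
  p <- e / rowSums(e)
  as.vector(t(p))
}

#' Multinomial logit log-likelihood and analytic gradient
#'
#' Sum over chosen alternatives of the log choice probability. The
#' analytic score, `sum_t (x_chosen - sum_j p_j x_j)`, is attached as
#' `attr(, "gradient")`.
#'
#' @param beta coefficient vector (aligned with the dataset's coded
#'   columns; names optional).
#' @param dataset a [choice_dataset()].
#' @return scalar log-likelihood with a `gradient` attribute.
#' @export
mnl_loglik <- function(beta, dataset) {
  ws <- if (is.list(dataset) && !is.null(dataset$X)) dataset
        else mnl_workspace(dataset)
  p <- mnl_prob(ws, beta)
  ll <- sum(log(p[ws$chosen]))
  g <- colSums(ws$X[ws$chosen, , drop = FALSE]) - colSums(p * ws$X)
  structure(ll, gradient = g)
}

mnl_hessian <- function(ws, beta) {
  p <- mnl_prob(ws, beta)
  B <- rowsum(p * ws$X, ws$task_of_row, reorder = FALSE)
  -(crossprod(ws$X * sqrt(p)) - crossprod(B))
}

# Columns without within-task contrast variation are unidentified.
check_identification <- function(ws) {
  B <- rowsum(ws$X, ws$task_of_row, reorder = FALSE) / ws$J
  Xc <- ws$X - B[ws$task_of_row, , drop = FALSE]
  q <- qr(Xc)
  if (q$rank < ncol(ws$X)) {
    drop <- colnames(ws$X)[q$pivot[(q$rank + 1L):ncol(ws$X)]]
    stop_dce("design matrix is collinear; unidentified columns: %s",
             paste(drop, collapse = ", "), class = "dcekit_collinear")
  }
  invisible(TRUE)
}

#' Fit a multinomial (conditional) logit model
#'
#' Maximum-likelihood estimation of the conditional logit by
#' Newton iterations with step halving (the log-likelihood is globally
#' concave). Standard errors come from the inverse observed information;
#' respondent-clustered sandwich errors are available by flag.
#'
#' @param dataset a [choice_dataset()].
#' @param start starting coefficients (default zeros).
#' @param tolerance convergence threshold on the gradient max-norm.
#' @param max_iter maximum Newton iterations.
#' @param cluster_se also compute respondent-clustered sandwich standard
#'   errors (`se_cluster` in the result)?
#' @return object of class `dce_fit` with estimates, standard errors,
#'   `vcov`, `log_likelihood`, `gradient_norm`, `converged`, `diverged`,
#'   counts and iteration metadata. Divergence (coefficients running away,
#'   as under separation) is flagged, with the partial result returned.
#' @export
fit_mnl <- function(dataset, start = NULL, tolerance = 1e-6, max_iter = 100L,
                    cluster_se = FALSE) {
  ws <- mnl_workspace(dataset)
  check_identification(ws)
  K <- ncol(ws$X)
  beta <- if (is.null(start)) numeric(K) else as.numeric(start)
  ll <- mnl_loglik(beta, ws)
  converged <- FALSE
  diverged <- FALSE
  iter <- 0L
  while (iter < max_iter) {
    iter <- iter + 1L
    g <- attr(ll, "gradient")
    if (max(abs(g)) < tolerance) { converged <- TRUE; break }
    H <- mnl_hessian(ws, beta)
    step <- tryCatch(solve(-H, g), error = function(e) g / max(1, sqrt(sum(g^2))))
    lam <- 1
    repeat {
      cand <- beta + lam * step
      ll_new <- mnl_loglik(cand, ws)
      if (as.numeric(ll_new) > as.numeric(ll) - 1e-12 || lam < 1e-8) break
      lam <- lam / 2
    }
    beta <- cand
    ll <- ll_new
    if (max(abs(beta)) > 50) { diverged <- TRUE; break }
  }
  # estimates running far outside the utility scale signal separation:
  # the gradient decays exponentially along the runaway direction, so a
  # small gradient norm alone cannot certify an interior maximum
  if (max(abs(beta)) > 10) diverged <- TRUE
  g <- attr(ll, "gradient")
  H <- mnl_hessian(ws, beta)
  vc <- tryCatch(solve(-H), error = function(e) matrix(NA_real_, K, K))
  nm <- colnames(ws$X)
  names(beta) <- nm
  dimnames(vc) <- list(nm, nm)
  se <- sqrt(pmax(diag(vc), 0))
  res <- structure(list(
    model = "MNL",
    estimates = beta, se = se, vcov = vc,
    log_likelihood = as.numeric(ll),
    gradient = g, gradient_norm = max(abs(g)),
    converged = converged && !diverged, diverged = diverged,
    iterations = iter,
    n_respondents = length(unique(ws$respondent)),
    n_tasks = ws$n_tasks, n_obs = nrow(ws$X),
    n_draws = NA_integer_, seed = NA_integer_,
    catalogue = attr(dataset, "catalogue"),
    attributes = attr(dataset, "attributes")
  ), class = "dce_fit")
  if (cluster_se) {
    p <- mnl_prob(ws, beta)
    Sc <- (ws$chosen - p) * ws$X
    Sr <- rowsum(Sc, ws$respondent)
    meat <- crossprod(Sr)
    vc_cl <- vc %*% meat %*% vc
    res$se_cluster <- sqrt(pmax(diag(vc_cl), 0))
    res$vcov_cluster <- vc_cl
  }
  res
}

#' @export
print.dce_fit <- function(x, ...) {
  cat(sprintf("<%s fit: %d respondents, %d tasks, LL = %.3f, %s>\n",
              x$model, x$n_respondents, x$n_tasks, x$log_likelihood,
              if (x$converged) "converged" else if (isTRUE(x$diverged))
                "DIVERGED" else "not converged"))
  tab <- data.frame(estimate = x$estimates, se = x$se)
  if (!is.null(x$sigma)) {
    tab <- rbind(tab, data.frame(estimate = x$sigma,
                                 se = x$sigma_se %||% rep(NA_real_, length(x$sigma)),
                                 row.names = paste0("sd.", names(x$sigma))))
  }
  print(round(tab, 4))
  invisible(x)
}

#' Per-level utilities implied by an effects-coded fit
#'
#' Expands estimated contrast coefficients into one utility per attribute
#' level: the reference (last-listed) level's utility is minus the sum of
#' its attribute's estimated contrasts, so level utilities sum to zero
#' within each attribute. Continuous attributes report their per-unit
#' coefficient; the opt-out constant is reported as is.
#'
#' @param fit a `dce_fit`, or a named coefficient vector.
#' @param attributes list of [attribute_spec()]; taken from the fit when
#'   available.
#' @return data frame with columns `attribute`, `level`, `utility`,
#'   `implied` (TRUE for reference levels whose utility is derived from the
#'   zero-sum constraint).
#' @export
level_utilities <- function(fit, attributes = NULL) {
  beta <- if (inherits(fit, "dce_fit")) fit$estimates else fit
  if (is.null(attributes) && inherits(fit, "dce_fit"))
    attributes <- fit$attributes
  if (is.null(attributes)) stop_dce("attribute specification required")
  out <- list()
  for (a in attributes) {
    if (a$coding == "effects") {
      L <- n_levels(a)
      cols <- paste0(a$name, ".", seq_len(L - 1L))
      if (!all(cols %in% names(beta)))
        stop_dce("fit lacks contrast columns for attribute '%s'", a$name)
      b <- beta[cols]
      out[[length(out) + 1L]] <- data.frame(
        attribute = a$name, level = a$levels,
        utility = c(unname(b), -sum(b)),
        implied = c(rep(FALSE, L - 1L), TRUE),
        stringsAsFactors = FALSE)
    } else {
      out[[length(out) + 1L]] <- data.frame(
        attribute = a$name, level = paste0("per ", a$units %||% "unit"),
        utility = unname(beta[[a$name]]), implied = FALSE,
        stringsAsFactors = FALSE)
    }
  }
  if ("opt_out" %in% names(beta))
    out[[length(out) + 1L]] <- data.frame(
      attribute = "opt_out", level = "Neither",
      utility = unname(beta[["opt_out"]]), implied = FALSE,
      stringsAsFactors = FALSE)
  do.call(rbind, out)
}

#' Export an estimation result as JSON
#'
#' @param fit a `dce_fit`.
#' @param path output path.
#' @return the path, invisibly.
#' @export
fit_to_json <- function(fit, path) {
  obj <- list(model = fit$model, estimates = as.list(fit$estimates),
              se = as.list(fit$se), vcov = fit$vcov,
              log_likelihood = fit$log_likelihood,
              gradient_norm = fit$gradient_norm, converged = fit$converged,
              n_respondents = fit$n_respondents, n_tasks = fit$n_tasks,
              n_draws = fit$n_draws, seed = fit$seed)
  if (!is.null(fit$sigma)) obj$sigma <- as.list(fit$sigma)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}
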