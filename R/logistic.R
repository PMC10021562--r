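#' Logistic regression by iteratively reweighted least squares
#'
#' Newton/IRLS maximisation of the Bernoulli log-likelihood with an
#' intercept prepended. Iterates until the gradient max-norm falls below
#' `tolerance`; step halving guards the likelihood ascent.
#'
#' @param X numeric design matrix (covariates only, no intercept column).
#' @param y binary outcome vector (0/1 or logical).
#' @param tolerance gradient max-norm threshold.
#' @param max_iter iteration cap.
#' @return list with `coefficients` (named, `(Intercept)` first), `vcov`,
#'   `se`, `log_likelihood`, `iterations`, `converged`, `n`.
#' @export
fit_logistic_irls <- function(X, y, tolerance = 1e-8, max_iter = 50L) {
  X <- as.matrix(X)
  y <- as.numeric(y)
  if (!all(y %in% c(0, 1))) stop_dce("outcome must be binary 0/1")
  if (nrow(X) != length(y)) stop_dce("X rows and y length differ")
  Xd <- cbind(`(Intercept)` = 1, X)
  q <- qr(Xd)
  if (q$rank < ncol(Xd)) {
    drop <- colnames(Xd)[q$pivot[(q$rank + 1L):ncol(Xd)]]
    stop_dce("design matrix rank deficient; offending columns: %s",
             paste(drop, collapse = ", "), class = "dcekit_collinear")
  }
  beta <- numeric(ncol(Xd))
  loglik <- function(b) {
    eta <- as.vector(Xd %*% b)
    sum(y * eta - log1p(exp(eta)))
  }
  ll <- loglik(beta)
  converged <- FALSE
  iter <- 0L
  while (iter < max_iter) {
    iter <- iter + 1L
    eta <- as.vector(Xd %*% beta)
    mu <- stats::plogis(eta)
    g <- crossprod(Xd, y - mu)
    if (max(abs(g)) < tolerance) { converged <- TRUE; break }
    w <- mu * (1 - mu)
    H <- crossprod(Xd * sqrt(pmax(w, 1e-12)))
    step <- solve(H, g)
    lam <- 1
    repeat {
      cand <- beta + lam * as.vector(step)
      ll_new <- loglik(cand)
      if (ll_new > ll - 1e-12 || lam < 1e-8) break
      lam <- lam / 2
    }
    beta <- cand
    ll <- ll_new
  }
  eta <- as.vector(Xd %*% beta)
  mu <- stats::plogis(eta)
  w <- mu * (1 - mu)
  H <- crossprod(Xd * sqrt(pmax(w, 1e-12)))
  vc <- solve(H)
  dimnames(vc) <- list(colnames(Xd), colnames(Xd))
  names(beta) <- colnames(Xd)
  list(coefficients = beta, vcov = vc, se = sqrt(diag(vc)),
       log_likelihood = ll, iterations = iter, converged = converged,
       n = length(y))
}

#' Detect complete separation of a binary outcome
#'
#' Flags covariates with a level that perfectly predicts the outcome
#' (monotone likelihood, so the logistic MLE is not finite). Only
#' categorical-like covariates (logical, factor/character, or numeric with
#' at most `max_levels` distinct values) are screened; a covariate is
#' flagged when some observed level co-occurs exclusively with one outcome
#' value while the outcome varies overall.
#'
#' @param X data frame or matrix of covariates.
#' @param y binary outcome.
#' @param max_levels distinct-value cap for treating a numeric covariate
#'   as categorical.
#' @return character vector of offending covariate names (empty if none).
#' @export
detect_separation <- function(X, y, max_levels = 4L) {
  X <- as.data.frame(X)
  y <- as.numeric(y)
  if (length(unique(y[!is.na(y)])) < 2L) return(character(0))
  offending <- character(0)
  for (nm in names(X)) {
    x <- X[[nm]]
    vals <- unique(x[!is.na(x)])
    categorical <- is.logical(x) || is.character(x) || is.factor(x) ||
      length(vals) <= max_levels
    if (!categorical) next
    for (v in vals) {
      sel <- !is.na(x) & x == v & !is.na(y)
      if (sum(sel) > 0L && length(unique(y[sel])) == 1L) {
        offending <- c(offending, nm)
        break
      }
    }
  }
  offending
}

risk_covariates <- c("age", "registered", "difficulty_350_bill",
                     "months_in_industry", "months_per_year",
                     "poor_wellbeing", "hunger_flag", "hiv_knowledge")

risk_outcomes <- c("ever_tourist_sex", "condom_last_sex", "sti_12m",
                   "alcohol_30d", "drugs_3m")

#' Fit the five risk-behaviour logistic regressions
#'
#' Fits multivariable logistic regressions of the five risk outcomes
#' (ever had sex with a tourist; condom use at last sex; STI symptoms in
#' the previous year; alcohol in the previous 30 days; drug use in the
#' previous 3 months) on the same eight covariates: age, registered
#' occupation, difficulty paying a GMD 350 bill, months working in the
#' industry, months per year working, poor wellbeing, moderate-or-high
#' household hunger, and HIV knowledge count. Each model uses listwise
#' deletion of records with any missing covariate or outcome; the drugs
#' model is restricted to respondents who ever used drugs
#' (`ever_used_drugs`). Covariates under complete separation are detected,
#' omitted from that model and recorded with a reason code. Odds ratios
#' are `exp(coefficient)` with Wald intervals; the pseudo R-squared is
#' McFadden's.
#'
#' @param profiles scored respondent data frame (see [score_profiles()]).
#' @param outcomes subset of outcomes to fit (default all five).
#' @param level confidence level for Wald intervals.
#' @return named list of `or_table` objects, one per outcome, each with
#'   elements `outcome`, `table` (OR, SE of the log-odds, CI, p),
#'   `n_observations`, `pseudo_r2`, `omitted` (named reasons),
#'   `log_likelihood`.
#' @export
fit_risk_models <- function(profiles, outcomes = risk_outcomes, level = 0.95) {
  profiles <- as.data.frame(profiles)
  missing_cov <- setdiff(risk_covariates, names(profiles))
  if (length(missing_cov))
    stop_dce("profiles lack covariates: %s", paste(missing_cov, collapse = ", "))
  z <- stats::qnorm(1 - (1 - level) / 2)
  out <- list()
  for (oc in outcomes) {
    if (!oc %in% names(profiles)) stop_dce("profiles lack outcome '%s'", oc)
    df <- profiles
    if (oc == "drugs_3m") {
      if (!"ever_used_drugs" %in% names(df))
        stop_dce("drugs model needs an 'ever_used_drugs' column")
      df <- df[df$ever_used_drugs %in% TRUE, , drop = FALSE]
    }
    df <- df[, c(oc, risk_covariates)]
    cc <- stats::complete.cases(df)
    df <- df[cc, , drop = FALSE]
    y <- as.numeric(df[[oc]])
    Xdf <- df[risk_covariates]
    omitted <- list()
    sep <- detect_separation(Xdf, y)
    for (nm in sep) omitted[[nm]] <- "complete_separation"
    keep <- setdiff(risk_covariates, sep)
    X <- data.matrix(Xdf[keep])
    if (nrow(X) < ncol(X) + 1L)
      stop_dce("model '%s': only %d complete cases for %d covariates",
               oc, nrow(X), ncol(X))
    fit <- fit_logistic_irls(X, y)
    b <- fit$coefficients
    se <- fit$se
    tab <- data.frame(
      term = names(b),
      odds_ratio = exp(b),
      se_log_odds = se,
      ci_lower = exp(b - z * se),
      ci_upper = exp(b + z * se),
      p_value = 2 * stats::pnorm(-abs(b / se)),
      stringsAsFactors = FALSE, row.names = NULL
    )
    p0 <- mean(y)
    ll0 <- sum(y * log(p0) + (1 - y) * log(1 - p0))
    out[[oc]] <- structure(list(
      outcome = oc,
      table = tab,
      n_observations = fit$n,
      pseudo_r2 = 1 - fit$log_likelihood / ll0,
      pseudo_r2_type = "McFadden",
      omitted = omitted,
      log_likelihood = fit$log_likelihood,
      converged = fit$converged,
      vcov = fit$vcov
    ), class = "or_table")
  }
  out
}

#' @export
print.or_table <- function(x, ...) {
  cat(sprintf("Logistic regression of %s (n = %d, McFadden R2 = %.3f)\n",
              x$outcome, x$n_observations, x$pseudo_r2))
  tab <- x$table
  tab$odds_ratio <- sprintf("%.3f", tab$odds_ratio)
  tab$se_log_odds <- sprintf("(%.4f)", tab$se_log_odds)
  tab$stars <- ifelse(x$table$p_value < 0.01, "***",
                      ifelse(x$table$p_value < 0.05, "**",
                             ifelse(x$table$p_value < 0.1, "*", "")))
  print(tab[, c("term", "odds_ratio", "se_log_odds", "stars")],
        row.names = FALSE)
  for (nm in names(x$omitted))
    cat(sprintf("  %s: Omitted (%s)\n", nm, x$omitted[[nm]]))
  invisible(x)
}

#' Export risk-correlate tables
#'
#' `risk_tables_to_json()` writes the machine-readable tables;
#' `write_risk_table()` writes a delimited table in the journal layout
#' (odds ratios with standard errors in parentheses, significance
#' markers, n and pseudo R-squared rows; separated covariates shown as
#' "Omitted").
#'
#' @param models list of `or_table` from [fit_risk_models()].
#' @param path output path.
#' @return the path, invisibly.
#' @export
risk_tables_to_json <- function(models, path) {
  obj <- lapply(models, function(m)
    list(outcome = m$outcome, table = m$table,
         n_observations = m$n_observations, pseudo_r2 = m$pseudo_r2,
         pseudo_r2_type = m$pseudo_r2_type, omitted = m$omitted))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' @rdname risk_tables_to_json
#' @export
write_risk_table <- function(models, path) {
  terms <- c(risk_covariates, "(Intercept)")
  fmt <- function(m, term) {
    if (term %in% names(m$omitted)) return(c("Omitted", ""))
    i <- match(term, m$table$term)
    if (is.na(i)) return(c("", ""))
    p <- m$table$p_value[i]
    stars <- if (p < 0.01) "***" else if (p < 0.05) "**" else if (p < 0.1) "*" else ""
    c(sprintf("%.3f%s", m$table$odds_ratio[i], stars),
      sprintf("(%.4f)", m$table$se_log_odds[i]))
  }
  rows <- list()
  for (term in terms) {
    vals <- lapply(models, fmt, term = term)
    rows[[length(rows) + 1L]] <- c(term, vapply(vals, `[`, character(1), 1))
    rows[[length(rows) + 1L]] <- c("", vapply(vals, `[`, character(1), 2))
  }
  rows[[length(rows) + 1L]] <-
    c("Observations", vapply(models, function(m) as.character(m$n_observations),
                             character(1)))
  rows[[length(rows) + 1L]] <-
    c("McFadden R-squared", vapply(models, function(m) sprintf("%.3f", m$pseudo_r2),
                                   character(1)))
  df <- as.data.frame(do.call(rbind, rows), stringsAsFactors = FALSE)
  names(df) <- c("term", vapply(models, `[[`, character(1), "outcome"))
  utils::write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}
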