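#' Willingness-to-accept for an attribute contrast
#'
#' Money-denominated compensation for a utility change, computed as
#' `-(delta beta) / beta_money` with the continuous (per-GMD) money
#' coefficient as denominator. A disliked change (negative utility
#' difference) with a positive money coefficient yields a positive
#' compensation. The ratio is invariant to rescaling all coefficients,
#' and to the effects-coding reference when the contrast is expressed
#' between two named levels. Uncertainty comes from Krinsky-Robb
#' simulation of the estimator's asymptotic normal distribution.
#'
#' @param fit a `dce_fit` from a model with a continuous money attribute.
#' @param contrast either a single coefficient name (e.g. `"opt_out"`),
#'   a weighted coefficient `list(coefficient =, weight =)` (e.g. weight
#'   -1 for the utility change of giving the alternative up), or
#'   `list(attribute =, from =, to =)` naming two levels of an
#'   effects-coded attribute; the utility difference is
#'   `utility(to) - utility(from)` on the implied level-utility scale.
#' @param money_key name of the continuous money coefficient (default
#'   `"money"`).
#' @param n_sim_draws Krinsky-Robb draws.
#' @param seed seed for the draws.
#' @param level confidence level of the percentile interval.
#' @param money_floor `|beta_money|` below which the ratio is flagged
#'   unstable.
#' @return object of class `wta_estimate`: contrast label, `point`,
#'   `ci_lower`, `ci_upper` (GMD), `unstable` flag, draw count and seed.
#' @export
wta <- function(fit, contrast, money_key = "money", n_sim_draws = 10000L,
                seed = 1L, level = 0.95, money_floor = 1e-8) {
  stopifnot(inherits(fit, "dce_fit"))
  beta <- fit$estimates
  if (!money_key %in% names(beta))
    stop_dce("no coefficient named '%s' in the fit", money_key)
  cat_ <- fit$catalogue
  if (!is.null(cat_)) {
    type <- cat_$type[match(money_key, cat_$column)]
    if (!is.na(type) && type != "continuous")
      stop_dce(paste0("'%s' is effects-coded in this fit; WTA per GMD is ",
                      "undefined. Refit with the money attribute coded ",
                      "continuous."), money_key)
  }
  cvec <- contrast_vector(fit, contrast)
  b_money <- beta[[money_key]]
  delta <- sum(cvec * beta[names(cvec)])
  point <- if (abs(b_money) < money_floor) NA_real_ else -delta / b_money
  ci <- krinsky_robb_ci(fit, contrast, money_key = money_key,
                        n_sim_draws = n_sim_draws, seed = seed,
                        level = level, money_floor = money_floor)
  structure(list(
    contrast = contrast_label(contrast),
    point = point,
    ci_lower = ci$lower, ci_upper = ci$upper,
    unstable = abs(b_money) < money_floor || ci$unstable,
    n_sim_draws = n_sim_draws, seed = seed, level = level,
    units = "GMD"
  ), class = "wta_estimate")
}

#' @export
print.wta_estimate <- function(x, ...) {
  cat(sprintf("WTA[%s] = %.1f GMD (%d%% CI %.1f to %.1f)%s\n", x$contrast,
              x$point, round(100 * x$level), x$ci_lower, x$ci_upper,
              if (x$unstable) " [UNSTABLE: money coefficient near zero]" else ""))
  invisible(x)
}

contrast_label <- function(contrast) {
  if (is.character(contrast) && length(contrast) == 1L) return(contrast)
  if (!is.null(contrast$coefficient))
    return(sprintf("%s x %s", contrast$coefficient, contrast$weight %||% 1))
  sprintf("%s: %s -> %s", contrast$attribute, contrast$from, contrast$to)
}

# Linear weights on the estimated coefficient vector realising the
# requested utility difference (implied reference levels expand to minus
# the sum of the attribute's contrasts).
contrast_vector <- function(fit, contrast) {
  beta <- fit$estimates
  if (is.character(contrast) && length(contrast) == 1L) {
    if (!contrast %in% names(beta))
      stop_dce("no coefficient named '%s'", contrast)
    return(stats::setNames(1, contrast))
  }
  stopifnot(is.list(contrast))
  if (!is.null(contrast$coefficient)) {
    if (!contrast$coefficient %in% names(beta))
      stop_dce("no coefficient named '%s'", contrast$coefficient)
    return(stats::setNames(contrast$weight %||% 1, contrast$coefficient))
  }
  if (is.null(contrast$attribute)) stop_dce("malformed contrast")
  attributes <- fit$attributes
  if (is.null(attributes))
    stop_dce("fit carries no attribute specification; level contrasts unavailable")
  a <- NULL
  for (cand in attributes) if (cand$name == contrast$attribute) a <- cand
  if (is.null(a)) stop_dce("unknown attribute '%s'", contrast$attribute)
  if (a$coding != "effects")
    stop_dce("level contrasts require an effects-coded attribute")
  L <- n_levels(a)
  cols <- paste0(a$name, ".", seq_len(L - 1L))
  level_weights <- function(label) {
    i <- match(label, a$levels)
    if (is.na(i)) stop_dce("unknown level '%s' of attribute '%s'",
                           label, a$name)
    w <- numeric(L - 1L)
    if (i < L) w[i] <- 1 else w[] <- -1
    stats::setNames(w, cols)
  }
  level_weights(contrast$to) - level_weights(contrast$from)
}

#' Krinsky-Robb percentile interval for a WTA ratio
#'
#' Draws coefficient vectors from the multivariate normal implied by the
#' estimates and their covariance, recomputes the WTA ratio for each draw,
#' and returns percentile bounds. A covariance matrix that is not positive
#' semidefinite is repaired by clipping negative eigenvalues to zero, with
#' a warning. Draws whose money coefficient falls below the numeric floor
#' make the interval unstable (flagged, computed from the finite draws).
#'
#' @inheritParams wta
#' @return list with `lower`, `upper`, `unstable`, `draws` (the simulated
#'   ratios).
#' @export
krinsky_robb_ci <- function(fit, contrast, money_key = "money",
                            n_sim_draws = 10000L, seed = 1L, level = 0.95,
                            money_floor = 1e-8) {
  stopifnot(inherits(fit, "dce_fit"))
  beta <- fit$estimates
  vc <- fit$vcov
  if (is.null(vc) || any(is.na(vc)))
    stop_dce("fit has no usable covariance matrix")
  vc <- vc[names(beta), names(beta), drop = FALSE]
  ev <- eigen((vc + t(vc)) / 2, symmetric = TRUE)
  if (any(ev$values < -1e-10)) {
    warning("covariance matrix not positive semidefinite; negative eigenvalues clipped")
    vc <- ev$vectors %*% diag(pmax(ev$values, 0), length(ev$values)) %*% t(ev$vectors)
    dimnames(vc) <- dimnames(fit$vcov[names(beta), names(beta)])
  }
  cvec <- contrast_vector(fit, contrast)
  draws <- local_seed(seed, MASS::mvrnorm(n_sim_draws, mu = beta, Sigma = vc))
  d_delta <- as.vector(draws[, names(cvec), drop = FALSE] %*% cvec)
  d_money <- draws[, money_key]
  bad <- abs(d_money) < money_floor
  ratio <- -d_delta / d_money
  ratio[bad] <- NA_real_
  qs <- if (all(bad)) c(NA_real_, NA_real_)
        else stats::quantile(ratio,
                             probs = c((1 - level) / 2, 1 - (1 - level) / 2),
                             na.rm = TRUE, names = FALSE)
  list(lower = qs[1], upper = qs[2], unstable = any(bad), draws = ratio)
}

#' Tabulate WTA estimates as JSON
#'
#' @param estimates named list of `wta_estimate` objects.
#' @param path output path.
#' @return the path, invisibly.
#' @export
wta_to_json <- function(estimates, path) {
  obj <- lapply(estimates, function(w)
    list(contrast = w$contrast, point_gmd = w$point,
         ci_lower_gmd = w$ci_lower, ci_upper_gmd = w$ci_upper,
         level = w$level, unstable = w$unstable,
         n_sim_draws = w$n_sim_draws, seed = w$seed))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}
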