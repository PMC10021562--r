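test_that("balanced 2x2 data with no association give OR 1", {
  X <- matrix(rep(c(0, 1), each = 20), ncol = 1,
              dimnames = list(NULL, "g"))
  y <- rep(c(0, 1), 20)
  fit <- fit_logistic_irls(X, y)
  expect_equal(unname(fit$coefficients[["g"]]), 0, tolerance = 1e-8)
  expect_equal(exp(unname(fit$coefficients[["g"]])), 1, tolerance = 1e-8)
})

test_that("a single binary covariate reproduces the 2x2 cross-product log odds ratio", {
  # cells: a = y1x1, b = y0x1, c = y1x0, d = y0x0
  a <- 17; b <- 9; c <- 6; d <- 22
  X <- matrix(c(rep(1, a + b), rep(0, c + d)), ncol = 1,
              dimnames = list(NULL, "x"))
  y <- c(rep(1, a), rep(0, b), rep(1, c), rep(0, d))
  fit <- fit_logistic_irls(X, y)
  expect_equal(unname(fit$coefficients[["x"]]), log(a * d / (b * c)),
               tolerance = 1e-7)
  expect_true(fit$converged)
})

test_that("IRLS agrees with an independent Nelder-Mead maximiser and with glm", {
  set.seed(8)
  X <- cbind(x1 = rnorm(20), x2 = rbinom(20, 1, 0.5))
  y <- rbinom(20, 1, plogis(-0.3 + 0.8 * X[, 1] - 0.5 * X[, 2]))
  fit <- fit_logistic_irls(X, y)
  # independent maximiser of the Bernoulli log-likelihood
  nll <- function(b) {
    eta <- b[1] + X %*% b[-1]
    -sum(y * eta - log1p(exp(eta)))
  }
  nm <- optim(c(0, 0, 0), nll, control = list(reltol = 1e-14, maxit = 5000))
  expect_equal(unname(fit$coefficients), nm$par, tolerance = 1e-3)
  # cross-check against the standard GLM fitter
  g <- glm(y ~ X, family = binomial())
  expect_equal(unname(fit$coefficients), unname(coef(g)), tolerance = 1e-6)
  expect_equal(unname(fit$se), unname(summary(g)$coefficients[, 2]),
               tolerance = 1e-4)
})

test_that("separation detection flags perfect predictors and spares independent ones", {
  y <- rep(c(0, 1), each = 20)
  X <- data.frame(same = y == 1, other = rep(c(TRUE, FALSE), 20))
  expect_equal(detect_separation(X, y), "same")

  set.seed(5)
  y2 <- rbinom(200, 1, 0.5)
  X2 <- data.frame(indep = rbinom(200, 1, 0.5) == 1)
  expect_length(detect_separation(X2, y2), 0L)

  # one-sided (quasi) separation: a level occurring only with y = 0
  x3 <- c(rep(0, 30), rep(1, 10))
  y3 <- c(rbinom(30, 1, 0.5), rep(0, 10))
  expect_equal(detect_separation(data.frame(v = x3), y3), "v")
})

test_that("rank-deficient designs are refused with the offending column named", {
  X <- cbind(a = rep(c(0, 1), 10), b = rep(c(0, 2), 10))
  y <- rbinom(20, 1, 0.5)
  err <- tryCatch(fit_logistic_irls(X, y), error = identity)
  expect_s3_class(err, "dcekit_collinear")
  expect_match(conditionMessage(err), "b")
})

test_that("coefficients of a generating logistic model are recovered with low bias", {
  cfg <- generator_config()
  spec <- cfg$outcome_model$ever_tourist_sex
  truth <- c(spec$intercept, as.numeric(spec$slopes))
  # bias is a property of the estimator, so average the estimates over
  # replicated samples of n = 5000 before comparing with the truth
  coefs <- sapply(1:3, function(r) {
    prof <- generate_survey(cfg, seed = 44 + r, n_respondents = 5000)
    X <- data.matrix(prof[cfg$outcome_model$covariates])
    fit_logistic_irls(X, as.numeric(prof$ever_tourist_sex))$coefficients
  })
  expect_lt(median(abs(rowMeans(coefs) - truth)), 0.05)
})

test_that("the five risk models run on scored profiles with per-model listwise deletion", {
  cfg <- generator_config()
  prof <- generate_survey(cfg, seed = 15, n_respondents = 242)
  models <- fit_risk_models(prof)
  expect_named(models, c("ever_tourist_sex", "condom_last_sex", "sti_12m",
                         "alcohol_30d", "drugs_3m"))
  expect_equal(models$ever_tourist_sex$n_observations, 242L)
  # drugs model restricted to ever-users
  expect_equal(models$drugs_3m$n_observations, sum(prof$ever_used_drugs))
  # odds ratios strictly positive and consistent with coefficients
  for (m in models) {
    expect_true(all(m$table$odds_ratio > 0))
    expect_true(all(m$table$ci_lower <= m$table$odds_ratio + 1e-12))
    expect_equal(m$pseudo_r2_type, "McFadden")
  }
  # injecting 2 records with a missing covariate drops that model's n by 2
  prof2 <- prof
  prof2$hunger_1[1:2] <- NA
  prof2 <- score_profiles(prof2)
  models2 <- fit_risk_models(prof2, outcomes = "ever_tourist_sex")
  expect_equal(models2$ever_tourist_sex$n_observations, 240L)
})

test_that("a drugs-model fixture with hunger implying use omits the hunger flag", {
  cfg <- generator_config()
  prof <- generate_survey(cfg, seed = 77, n_respondents = 242)
  prof$ever_used_drugs <- TRUE
  set.seed(101)
  # every respondent reporting hunger also reports recent drug use
  prof$drugs_3m[prof$hunger_flag] <- TRUE
  prof$drugs_3m[!prof$hunger_flag] <-
    rbinom(sum(!prof$hunger_flag), 1, 0.5) == 1
  models <- fit_risk_models(prof, outcomes = "drugs_3m")
  m <- models$drugs_3m
  expect_true("hunger_flag" %in% names(m$omitted))
  expect_equal(m$omitted$hunger_flag, "complete_separation")
  expect_false("hunger_flag" %in% m$table$term)
  expect_true(m$converged)
})

test_that("risk tables export to JSON and a journal-style delimited table", {
  cfg <- generator_config()
  prof <- generate_survey(cfg, seed = 18, n_respondents = 242)
  models <- fit_risk_models(prof)
  jf <- tempfile(fileext = ".json")
  tf <- tempfile(fileext = ".tsv")
  risk_tables_to_json(models, jf)
  write_risk_table(models, tf)
  parsed <- jsonlite::read_json(jf)
  expect_named(parsed, names(models))
  tab <- read.delim(tf, check.names = FALSE)
  expect_equal(ncol(tab), 6L)
  expect_true("Observations" %in% tab$term)
})
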