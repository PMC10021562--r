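test_that("systematic utility is the aligned dot product", {
  row <- c(a.1 = 1, a.2 = -1, money = 500, opt_out = 0)
  zero <- setNames(rep(0, 4), names(row))
  expect_equal(systematic_utility(zero, row), 0)

  # an opt-out row scores exactly the opt-out constant
  oo <- c(a.1 = 0, a.2 = 0, money = 0, opt_out = 1)
  beta <- c(a.1 = 2.4, a.2 = -9, money = 0.1, opt_out = 0.522)
  expect_equal(systematic_utility(beta, oo), 0.522)

  set.seed(1)
  for (i in 1:10) {
    b <- setNames(rnorm(4), names(row))
    x <- setNames(rnorm(4), sample(names(row)))   # shuffled names
    manual <- 0
    for (nm in names(b)) manual <- manual + b[[nm]] * x[[nm]]
    expect_equal(systematic_utility(b, x), manual)
  }
  expect_dce_error(systematic_utility(c(a = 1), c(b = 1)), "mismatch")
})

test_that("choice probabilities are a stabilised softmax", {
  X <- matrix(0, 3, 2, dimnames = list(NULL, c("x", "opt_out")))
  b <- c(x = 1, opt_out = 1)
  expect_equal(choice_probabilities(b, X), rep(1 / 3, 3))

  # utility difference ln 2 -> (2/3, 1/3)
  X2 <- matrix(c(log(2), 0), 2, 1, dimnames = list(NULL, "x"))
  expect_equal(choice_probabilities(c(x = 1), X2), c(2 / 3, 1 / 3))

  # translation invariance and overflow safety
  X3 <- matrix(rnorm(6), 3, 2, dimnames = list(NULL, c("x", "opt_out")))
  p <- choice_probabilities(b, X3)
  expect_equal(choice_probabilities(b, X3 + 1000), p)
  expect_true(all(p > 0) && abs(sum(p) - 1) < 1e-12)
})

test_that("log-likelihood at zero coefficients is N log(1/J) and doubles under duplication", {
  cfg <- generator_config()
  des <- pilot_design(cfg$attributes, n_tasks = 4, seed = 3)
  ds <- generate_choices(cfg, des, seed = 8, n_respondents = 10)
  ll0 <- mnl_loglik(numeric(13), ds)
  expect_equal(as.numeric(ll0), 40 * log(1 / 3))

  df2 <- as.data.frame(ds)
  dup <- df2
  dup$respondent_id <- dup$respondent_id + 100
  ds2 <- choice_dataset(rbind(df2, dup), attr(ds, "catalogue"),
                        attr(ds, "attributes"))
  b <- rnorm(13) / 4
  expect_equal(as.numeric(mnl_loglik(b, ds2)),
               2 * as.numeric(mnl_loglik(b, ds)))
})

test_that("the analytic gradient matches central finite differences", {
  cfg <- generator_config()
  des <- pilot_design(cfg$attributes, n_tasks = 3, seed = 6)
  ds <- generate_choices(cfg, des, seed = 2, n_respondents = 15)
  set.seed(42)
  for (i in 1:3) {
    b <- rnorm(13) / 3
    g <- attr(mnl_loglik(b, ds), "gradient")
    h <- 1e-6
    gnum <- vapply(seq_along(b), function(k) {
      bp <- b; bp[k] <- bp[k] + h
      bm <- b; bm[k] <- bm[k] - h
      (as.numeric(mnl_loglik(bp, ds)) - as.numeric(mnl_loglik(bm, ds))) / (2 * h)
    }, numeric(1))
    expect_lt(max(abs(g - gnum)), 1e-6)
  }
})

test_that("the MNL Hessian is negative semidefinite wherever evaluated", {
  cfg <- generator_config()
  des <- pilot_design(cfg$attributes, n_tasks = 3, seed = 5)
  ds <- generate_choices(cfg, des, seed = 4, n_respondents = 8)
  ws <- dcekit:::mnl_workspace(ds)
  set.seed(7)
  for (i in 1:5) {
    H <- dcekit:::mnl_hessian(ws, rnorm(13))
    ev <- eigen((H + t(H)) / 2, symmetric = TRUE, only.values = TRUE)$values
    expect_true(all(ev < 1e-8))
  }
})

test_that("IIA holds: probability ratios ignore a third alternative's attributes", {
  b <- c(x = 0.8, opt_out = -0.2)
  X <- matrix(c(1, 0.2, 0,
                0, 0, 1), 3, 2, dimnames = list(NULL, c("x", "opt_out")))
  X2 <- X
  X2[3, "x"] <- 5     # edit only the third alternative
  p1 <- choice_probabilities(b, X)
  p2 <- choice_probabilities(b, X2)
  expect_equal(p1[1] / p1[2], p2[1] / p2[2])
})

test_that("a one-parameter fit matches an independent grid-search maximiser", {
  # 6 tasks, 2 alternatives differing in one binary column
  X <- matrix(rep(c(1, 0), 6), ncol = 1, dimnames = list(NULL, "x"))
  chosen <- c(1, 0, 1, 0, 0, 1, 1, 0, 1, 0, 1, 0)   # alt 1 chosen 5/6
  ds <- make_dataset(X, chosen, J = 2)
  fit <- fit_mnl(ds)
  grid <- seq(-4, 4, by = 1e-4)
  llg <- vapply(grid, function(b) {
    p1 <- exp(b) / (exp(b) + 1)
    sum(log(ifelse(chosen[seq(1, 12, 2)] == 1, p1, 1 - p1)))
  }, numeric(1))
  expect_equal(unname(fit$estimates[["x"]]), grid[which.max(llg)],
               tolerance = 1e-3)
  expect_true(fit$converged)
  expect_lt(fit$gradient_norm, 1e-6)
})

test_that("parameters generating the data are recovered within sampling error", {
  cfg <- generator_config()
  des <- search_efficient_design(cfg$attributes, cfg$beta, n_tasks = 8,
                                 seed = 21, n_restarts = 1)
  ds <- generate_choices(cfg, des, seed = 13, n_respondents = 2000)
  fit <- fit_mnl(ds)
  expect_true(fit$converged)
  # each coefficient within 4 SEs of truth at n = 2000 x 8
  expect_true(all(abs(fit$estimates - cfg$beta) < 4 * fit$se))
})

test_that("a never-chosen alternative with a dedicated constant is flagged as divergent", {
  cfg <- generator_config()
  des <- pilot_design(cfg$attributes, n_tasks = 8, seed = 10)
  # opt-out never chosen: force choices onto alternative 1
  ds <- generate_choices(cfg, des, seed = 3, n_respondents = 40)
  df <- as.data.frame(ds)
  df$chosen <- as.integer(df$alt_id == 1)
  ds2 <- choice_dataset(df, attr(ds, "catalogue"), attr(ds, "attributes"))
  fit <- fit_mnl(ds2, max_iter = 200)
  expect_false(fit$converged && !fit$diverged)
})

test_that("collinear coded columns are reported with their names", {
  X <- cbind(x = rep(c(1, 0), 5), y = rep(c(2, 0), 5))
  chosen <- rep(c(1, 0), 5)
  ds <- make_dataset(X, chosen, J = 2)
  err <- tryCatch(fit_mnl(ds), error = identity)
  expect_s3_class(err, "dcekit_collinear")
  expect_match(conditionMessage(err), "y")
})

test_that("clustered standard errors are computed and positive", {
  cfg <- generator_config()
  des <- pilot_design(cfg$attributes, n_tasks = 8, seed = 31)
  ds <- generate_choices(cfg, des, seed = 17, n_respondents = 60)
  fit <- fit_mnl(ds, cluster_se = TRUE)
  expect_length(fit$se_cluster, 13L)
  expect_true(all(fit$se_cluster > 0))
})

test_that("implied level utilities sum to zero within each attribute", {
  cfg <- generator_config()
  des <- pilot_design(cfg$attributes, n_tasks = 8, seed = 12)
  ds <- generate_choices(cfg, des, seed = 19, n_respondents = 50)
  fit <- fit_mnl(ds)
  lu <- level_utilities(fit)
  sums <- tapply(lu$utility[lu$attribute != "opt_out"],
                 lu$attribute[lu$attribute != "opt_out"], sum)
  expect_true(all(abs(sums) < 1e-10))
})
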