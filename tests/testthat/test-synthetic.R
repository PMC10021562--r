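test_that("a dominant coefficient forces its alternative to be chosen everywhere", {
  cfg <- generator_config()
  cfg$beta[] <- 0
  cfg$beta[["opt_out"]] <- 50
  des <- pilot_design(cfg$attributes, n_tasks = 8, seed = 1)
  ds <- generate_choices(cfg, des, seed = 9, n_respondents = 30)
  df <- as.data.frame(ds)
  expect_true(all(df$chosen[df$opt_out == 1] == 1))
})

test_that("under all-zero parameters the opt-out share sits near 1/3", {
  cfg <- generator_config()
  cfg$beta[] <- 0
  des <- pilot_design(cfg$attributes, n_tasks = 8, seed = 2)
  ds <- generate_choices(cfg, des, seed = 31, n_respondents = 242)
  df <- as.data.frame(ds)
  share <- mean(df$chosen[df$opt_out == 1])
  n <- 242 * 8
  mc_sd <- sqrt((1 / 3) * (2 / 3) / n)
  expect_lt(abs(share - 1 / 3), 3 * mc_sd)
})

test_that("empirical choice shares converge to the analytic logit probabilities", {
  cfg <- generator_config()
  des <- pilot_design(cfg$attributes, n_tasks = 1, seed = 3)
  X <- dcekit:::coded_task_matrices(des)[[1]]
  p_true <- choice_probabilities(cfg$beta, X)
  R <- 1e5
  ds <- generate_choices(cfg, des, seed = 77, n_respondents = R)
  counts <- tapply(ds$chosen, ds$alt_id, sum)
  expect_lt(max(abs(counts / R - p_true)), 0.01)
})

test_that("choice generation is byte-identical for a seed and distinct across seeds", {
  cfg <- generator_config()
  des <- pilot_design(cfg$attributes, n_tasks = 8, seed = 4)
  a <- generate_choices(cfg, des, seed = 5, n_respondents = 20)
  b <- generate_choices(cfg, des, seed = 5, n_respondents = 20)
  c <- generate_choices(cfg, des, seed = 6, n_respondents = 20)
  expect_identical(as.data.frame(a), as.data.frame(b))
  expect_false(identical(as.data.frame(a)$chosen, as.data.frame(c)$chosen))
  # generated data always satisfy the dataset invariants (constructor ran)
  expect_s3_class(a, "choice_dataset")
})

test_that("mixed-coefficient generation respects the panel structure", {
  cfg <- generator_config()
  cfg$sigma[] <- 2
  cfg$beta[] <- 0
  des <- pilot_design(cfg$attributes, n_tasks = 8, seed = 8)
  ds <- generate_choices(cfg, des, seed = 3, n_respondents = 200)
  # strong taste heterogeneity induces within-respondent persistence:
  # the same respondent picks the opt-out more consistently than chance
  df <- as.data.frame(ds)
  oo <- df[df$opt_out == 1, ]
  per_resp <- tapply(oo$chosen, oo$respondent_id, mean)
  expect_gt(var(per_resp), (1 / 3) * (2 / 3) / 8)
})

test_that("survey marginals match their configured targets at n = 10,000", {
  cfg <- generator_config()
  sv <- generate_survey(cfg, seed = 3, n_respondents = 10000)
  expect_lt(abs(mean(sv$age) - 39.2), 0.3)
  expect_lt(abs(mean(sv$registered) - 0.40), 0.02)
  expect_lt(abs(mean(sv$hunger_flag) - 0.15), 0.02)
  expect_lt(abs(mean(sv$who5_total) - 16.2), 0.2)
  expect_lt(abs(mean(sv$hiv_knowledge == 9) - 0.25), 0.02)
  expect_lt(abs(mean(sv$hiv_knowledge < 6) - 0.47), 0.02)
  expect_lt(abs(mean(sv$months_per_year) - 7.4), 0.2)
  # item-level consistency
  expect_true(all(rowSums(sv[paste0("who5_", 1:5)]) == sv$who5_total))
  expect_true(all(sv[paste0("who5_", 1:5)] <= 5))
})

test_that("a zero-slope outcome model reproduces its intercept-implied prevalence", {
  cfg <- generator_config()
  cfg$outcome_model$ever_tourist_sex <- list(intercept = qlogis(0.3),
                                             slopes = rep(0, 8))
  sv <- generate_survey(cfg, seed = 21, n_respondents = 10000)
  expect_lt(abs(mean(sv$ever_tourist_sex) - 0.3), 3 * sqrt(0.3 * 0.7 / 10000) + 0.005)
})

test_that("recovery reporting is complete and excludes non-convergent replicates", {
  cfg <- generator_config()
  des <- search_efficient_design(cfg$attributes, cfg$beta, n_tasks = 8,
                                 seed = 41, n_restarts = 1)
  rec <- recovery_experiment(cfg, des, n_replicates = 4, seed = 90,
                             n_respondents = 150)
  expect_s3_class(rec, "recovery_report")
  expect_equal(nrow(rec$summary), 18L)   # 17 level utilities + opt-out
  expect_equal(rec$n_converged + rec$n_excluded, 4L)
  expect_true(all(c("truth", "mean", "bias", "empirical_se", "mc_se") %in%
                  names(rec$summary)))
  # deterministic given the seed schedule
  rec2 <- recovery_experiment(cfg, des, n_replicates = 4, seed = 90,
                              n_respondents = 150)
  expect_identical(rec$estimates, rec2$estimates)
})

test_that("doubling the sample shrinks the empirical SE roughly as root-n", {
  cfg <- generator_config()
  des <- search_efficient_design(cfg$attributes, cfg$beta, n_tasks = 8,
                                 seed = 51, n_restarts = 1)
  r1 <- recovery_experiment(cfg, des, n_replicates = 50, seed = 7,
                            n_respondents = 120)
  r2 <- recovery_experiment(cfg, des, n_replicates = 50, seed = 107,
                            n_respondents = 240)
  ratio <- median(r2$summary$empirical_se / r1$summary$empirical_se)
  expect_gt(ratio, 0.6)
  expect_lt(ratio, 0.82)
})
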