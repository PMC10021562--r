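test_that("D-error matches an independently coded Fisher-information computation", {
  atts <- list(binary_attribute())
  # 2 tasks, 2 alternatives, no opt-out: alternatives differ in each task
  prof <- array(c(1L, 2L,   # task 1 alts
                  2L, 1L),  # task 2 alts
                dim = c(2, 2, 1))
  des <- choice_design(atts, prof, has_opt_out = FALSE)

  for (beta in list(c(0, 0), c(0.5, -0.2))) {
    Xs <- dcekit:::coded_task_matrices(des)
    oracle <- brute_force_information(lapply(Xs, unname), beta)
    K <- length(beta)
    expect_equal(as.numeric(d_error(des, beta)),
                 det(oracle)^(-1 / K), tolerance = 1e-10)
  }
})

test_that("identical profile alternatives give a singular, undefined D-error", {
  atts <- toy_attributes()
  prof <- array(rep(c(1L, 2L), each = 2 * 8), dim = c(8, 2, 2))
  prof[, 2, ] <- prof[, 1, ]    # both alternatives identical in every task
  des <- choice_design(atts, prof, has_opt_out = TRUE)
  de <- d_error(des, numeric(4))
  expect_true(is.infinite(de))
  expect_true(attr(de, "singular"))
})

test_that("zero-scaled priors reproduce the utility-neutral D-error and task order is irrelevant", {
  atts <- toy_attributes()
  set.seed(4)
  prof <- array(sample.int(2L, 8 * 2 * 2, replace = TRUE), dim = c(8, 2, 2))
  prof[, , 2] <- sample.int(3L, 16, replace = TRUE)
  des <- choice_design(atts, prof)
  priors <- c(0.4, -0.3, 0.2, 0.7)
  expect_equal(as.numeric(d_error(des, priors * 0)),
               as.numeric(d_error(des, numeric(4))))
  perm <- sample(8)
  des_perm <- choice_design(atts, prof[perm, , , drop = FALSE])
  expect_equal(as.numeric(d_error(des_perm, priors)),
               as.numeric(d_error(des, priors)), tolerance = 1e-12)
})

test_that("coordinate exchange attains the exhaustive minimum on a small space", {
  atts <- list(binary_attribute("z"))
  priors <- c(0.3, -0.1)
  # 2 tasks x 2 alternatives, 2 candidate profiles: 2^4 = 16 candidate designs
  combos <- expand.grid(1:2, 1:2, 1:2, 1:2)
  d_all <- apply(combos, 1L, function(v) {
    prof <- array(as.integer(v), dim = c(2, 2, 1))
    as.numeric(d_error(choice_design(atts, prof, has_opt_out = TRUE), priors))
  })
  best_exhaustive <- min(d_all)
  found <- search_efficient_design(atts, priors, n_tasks = 2,
                                   n_alternatives = 2, seed = 11,
                                   n_restarts = 3)
  expect_equal(found$meta$d_error, best_exhaustive, tolerance = 1e-10)
})

test_that("the exchange search is seed-deterministic with a monotone trajectory", {
  atts <- toy_attributes()
  priors <- c(0.2, -0.4, 0.1, 0.3)
  d1 <- search_efficient_design(atts, priors, n_tasks = 4, seed = 7,
                                n_restarts = 2)
  d2 <- search_efficient_design(atts, priors, n_tasks = 4, seed = 7,
                                n_restarts = 2)
  expect_identical(d1$profiles, d2$profiles)
  expect_true(all(diff(d1$meta$trajectory) <= 1e-12))
  # improvement over the seeded random start it began from
  start <- pilot_design(atts, 4, 2, TRUE, seed = 7)
  expect_lte(d1$meta$d_error, as.numeric(d_error(start, priors)))
})

test_that("the study-shape search yields a valid 8-task design with opt-out", {
  atts <- study_attributes()
  des <- search_efficient_design(atts, numeric(13), n_tasks = 8, seed = 3,
                                 n_restarts = 1)
  expect_s3_class(des, "choice_design")
  expect_equal(des$n_tasks, 8L)
  expect_equal(des$n_profile_alts, 2L)
  expect_true(des$has_opt_out)
  expect_true(is.finite(des$meta$d_error))
  Xs <- dcekit:::coded_task_matrices(des)
  expect_equal(nrow(Xs[[1]]), 3L)
  # opt-out row: zeros in attribute columns, 1 in the constant
  oo <- Xs[[1]][3, ]
  expect_equal(unname(oo[["opt_out"]]), 1)
  expect_true(all(oo[setdiff(names(oo), "opt_out")] == 0))
})

test_that("design export produces a readable questionnaire and JSON", {
  atts <- toy_attributes()
  des <- search_efficient_design(atts, numeric(4), n_tasks = 3, seed = 1,
                                 n_restarts = 1)
  jf <- tempfile(fileext = ".json")
  qf <- tempfile(fileext = ".tsv")
  design_to_json(des, jf)
  write_questionnaire(des, qf)
  parsed <- jsonlite::read_json(jf)
  expect_equal(parsed$n_tasks, 3L)
  q <- read.delim(qf)
  expect_equal(nrow(q), 3L * 3L)   # 2 profiles + opt-out per task
  expect_true(all(q$risk[q$alternative == 3] == "Neither"))
})

test_that("a singular candidate space is an explicit failure", {
  a <- binary_attribute("w")
  cand <- matrix(1L, nrow = 1)   # only one profile available
  expect_dce_error(
    search_efficient_design(list(a), c(0, 0), n_tasks = 2, seed = 1,
                            candidates = cand),
    "singular")
})
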