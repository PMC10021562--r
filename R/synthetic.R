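# Synthetic study generator: choice data under the random-utility model
# and survey records with marginals calibrated to the study sample. Serves
# as the Monte Carlo parameter-recovery harness for the estimators.

#' Load a data-generating configuration
#'
#' Reads the generator defaults (attribute list, true level utilities,
#' random-coefficient SDs, covariate marginals, outcome models) shipped in
#' `inst/extdata`, or a user file of the same shape. True level utilities
#' must satisfy the effects-coding zero-sum constraint within each
#' attribute; they are converted internally to the coded coefficient
#' vector (contrasts + opt-out constant).
#'
#' @param path generator YAML (default: packaged `generator_defaults.yaml`).
#' @param attributes_path attribute YAML (default: packaged
#'   `tourist_partnership_attributes.yaml`).
#' @return object of class `generator_config`.
#' @export
generator_config <- function(path = NULL, attributes_path = NULL) {
  if (is.null(path))
    path <- system.file("extdata", "generator_defaults.yaml", package = "dcekit")
  if (is.null(attributes_path))
    attributes_path <- system.file("extdata", "tourist_partnership_attributes.yaml",
                                   package = "dcekit")
  raw <- yaml::read_yaml(path)
  dc <- read_design_config(attributes_path)
  attributes <- dc$attributes
  cm <- raw$choice_model
  lu <- cm$level_utilities
  beta <- numeric(0)
  for (a in attributes) {
    vals <- as.numeric(lu[[a$name]])
    if (length(vals) != n_levels(a))
      stop_dce("level_utilities for '%s' has %d values, attribute has %d levels",
               a$name, length(vals), n_levels(a))
    if (abs(sum(vals)) > 1e-8)
      stop_dce("level utilities of '%s' must sum to zero (effects coding), got %g",
               a$name, sum(vals))
    b <- vals[-n_levels(a)]
    names(b) <- paste0(a$name, ".", seq_along(b))
    beta <- c(beta, b)
  }
  beta <- c(beta, opt_out = as.numeric(cm$opt_out_constant))
  sigma <- cm$sigma %||% 0
  if (length(sigma) == 1L) sigma <- rep(as.numeric(sigma), length(beta))
  sigma <- stats::setNames(as.numeric(sigma), names(beta))
  if (any(sigma < 0)) stop_dce("sigma entries must be >= 0")
  structure(list(
    attributes = attributes,
    design_settings = dc$design,
    beta = beta,
    sigma = sigma,
    level_utilities = lu,
    opt_out_constant = as.numeric(cm$opt_out_constant),
    n_respondents = as.integer(cm$n_respondents %||% 242L),
    covariate_model = raw$covariate_model,
    outcome_model = raw$outcome_model
  ), class = "generator_config")
}

#' @export
print.generator_config <- function(x, ...) {
  cat(sprintf("<generator_config: %d respondents, %d attributes, %s taste heterogeneity>\n",
              x$n_respondents, length(x$attributes),
              if (any(x$sigma > 0)) "with" else "no"))
  invisible(x)
}

#' Simulate choice data under the random-utility model
#'
#' For every respondent and task, utilities are the systematic coded part
#' plus independent Gumbel (type-I extreme value) draws obtained by
#' inverse-CDF of seeded uniforms; the chosen alternative is the argmax,
#' which makes the simulated choice probabilities exactly multinomial
#' logit. When any `sigma` entry is positive, each respondent receives one
#' normal coefficient vector `b + s * z_r` spanning all of their tasks
#' (panel mixing). Byte-identical output for identical seeds.
#'
#' @param config a [generator_config()].
#' @param design a [choice_design()] matching the config's attributes.
#' @param seed integer seed.
#' @param n_respondents override of the configured respondent count.
#' @return a [choice_dataset()].
#' @export
generate_choices <- function(config, design, seed = 1L,
                             n_respondents = NULL) {
  stopifnot(inherits(config, "generator_config"),
            inherits(design, "choice_design"))
  n_resp <- as.integer(n_respondents %||% config$n_respondents)
  if (n_resp < 1L) stop_dce("n_respondents must be >= 1")
  Xs <- coded_task_matrices(design)
  Xd <- do.call(rbind, Xs)                       # (T*J) x K, task-major
  K <- ncol(Xd)
  if (length(config$beta) != K)
    stop_dce("config coefficients (%d) do not match design columns (%d)",
             length(config$beta), K)
  Tn <- design$n_tasks
  J <- nrow(Xs[[1]])
  mixed <- any(config$sigma > 0)
  rows_per_resp <- Tn * J
  local_seed(seed, {
    chosen <- integer(n_resp * rows_per_resp)
    V_fixed <- as.vector(Xd %*% config$beta)
    if (mixed) {
      for (r in seq_len(n_resp)) {
        br <- config$beta + config$sigma * stats::rnorm(K)
        U <- as.vector(Xd %*% br) + rgumbel(rows_per_resp)
        pick <- max.col(t(matrix(U, nrow = J)), ties.method = "first")
        idx <- (r - 1L) * rows_per_resp + (seq_len(Tn) - 1L) * J + pick
        chosen[idx] <- 1L
      }
    } else {
      U <- rep(V_fixed, n_resp) + rgumbel(n_resp * rows_per_resp)
      pick <- max.col(t(matrix(U, nrow = J)), ties.method = "first")
      idx <- (seq_len(n_resp * Tn) - 1L) * J + pick
      chosen[idx] <- 1L
    }
    df <- data.frame(
      respondent_id = rep(seq_len(n_resp), each = rows_per_resp),
      task_id = rep(rep(seq_len(Tn), each = J), times = n_resp),
      alt_id = rep(seq_len(J), times = n_resp * Tn),
      chosen = chosen
    )
    df <- cbind(df, as.data.frame(Xd[rep(seq_len(rows_per_resp), n_resp), ,
                                     drop = FALSE],
                                  check.names = FALSE))
    choice_dataset(df, coding_catalogue(design$attributes),
                   design$attributes)
  })
}

# Allocate an integer total over k items each capped at `cap`, uniformly
# at random among feasible increments.
allocate_items <- function(total, k, cap) {
  x <- integer(k)
  while (total > 0L) {
    open <- which(x < cap)
    i <- if (length(open) == 1L) open else sample(open, 1L)
    x[i] <- x[i] + 1L
    total <- total - 1L
  }
  x
}

#' Simulate respondent survey records
#'
#' Draws covariates independently per respondent from the configured
#' marginal distributions (age truncated normal; registered occupation,
#' bill-difficulty, hunger flag Bernoulli; income and industry tenure
#' lognormal; months-per-year clamped normal; WHO-5 totals discretised
#' normal split into items; HIV knowledge drawn by category then count),
#' derives the scored covariates, then draws the five risk outcomes from
#' Bernoulli distributions whose logits are the configured linear
#' predictors (the drugs outcome only among ever-users of drugs).
#'
#' @param config a [generator_config()].
#' @param seed integer seed.
#' @param n_respondents override of the configured respondent count.
#' @return scored respondent data frame (see [score_profiles()]).
#' @export
generate_survey <- function(config, seed = 1L, n_respondents = NULL) {
  stopifnot(inherits(config, "generator_config"))
  n <- as.integer(n_respondents %||% config$n_respondents)
  cm <- config$covariate_model
  local_seed(seed, {
    age <- pmax(stats::rnorm(n, cm$age$mean, cm$age$sd), cm$age$min %||% 18)
    registered <- stats::runif(n) < cm$registered$prob
    occupation <- ifelse(registered,
                         ifelse(stats::runif(n) < 0.5, "tour_guide", "tourist_taxi_driver"),
                         sample(c("juice_presser", "bumster", "restaurant_bar",
                                  "other"), n, replace = TRUE,
                                prob = c(0.18, 0.14, 0.08, 0.60)))
    difficulty <- stats::runif(n) < cm$difficulty_350_bill$prob
    inc <- cm$income_monthly
    income <- stats::rlnorm(n, log(inc$medianlog),
                            sqrt(2 * log(inc$mean / inc$medianlog)))
    mi <- cm$months_in_industry
    months_ind <- stats::rlnorm(n, log(mi$median), sqrt(2 * log(mi$mean / mi$median)))
    mpy <- cm$months_per_year
    months_py <- pmin(pmax(stats::rnorm(n, mpy$mean, mpy$sd), mpy$min %||% 0),
                      mpy$max %||% 12)
    who5_total <- pmin(pmax(round(stats::rnorm(n, cm$who5_total$mean,
                                               cm$who5_total$sd)), 0), 25)
    who5 <- t(vapply(who5_total, allocate_items, integer(5), k = 5L, cap = 5L))
    hflag <- stats::runif(n) < cm$hunger_flag$prob
    hscore <- integer(n)
    hscore[hflag] <- sample(2:6, sum(hflag), replace = TRUE,
                            prob = c(0.45, 0.25, 0.15, 0.10, 0.05))
    hscore[!hflag] <- sample(0:1, sum(!hflag), replace = TRUE,
                             prob = c(0.75, 0.25))
    hunger <- t(vapply(hscore, allocate_items, integer(3), k = 3L, cap = 2L))
    hk <- cm$hiv_knowledge
    hcat <- sample(c("low", "mid", "very_high"), n, replace = TRUE,
                   prob = c(hk$p_low, hk$p_mid, hk$p_very_high))
    hcount <- integer(n)
    hcount[hcat == "low"] <- sample(0:5, sum(hcat == "low"), replace = TRUE,
                                    prob = c(0.05, 0.10, 0.15, 0.20, 0.25, 0.25))
    hcount[hcat == "mid"] <- sample(6:8, sum(hcat == "mid"), replace = TRUE)
    hcount[hcat == "very_high"] <- 9L
    hiv <- t(vapply(hcount, function(k) {
      v <- logical(9); v[sample.int(9L, k)] <- TRUE; as.integer(v)
    }, integer(9)))
    ever_drugs <- stats::runif(n) < cm$ever_used_drugs$prob

    profiles <- data.frame(
      respondent_id = seq_len(n),
      age = age, registered = registered, occupation = occupation,
      difficulty_350_bill = difficulty, income_monthly = income,
      months_in_industry = months_ind, months_per_year = months_py,
      ever_used_drugs = ever_drugs
    )
    colnames(who5) <- paste0("who5_", 1:5)
    colnames(hunger) <- paste0("hunger_", 1:3)
    colnames(hiv) <- paste0("hiv_", 1:9)
    profiles <- cbind(profiles, who5, hunger, hiv)
    profiles <- score_profiles(profiles)

    om <- config$outcome_model
    covs <- om$covariates
    Xo <- data.matrix(profiles[covs])
    for (oc in setdiff(names(om), "covariates")) {
      spec <- om[[oc]]
      lp <- spec$intercept + as.vector(Xo %*% as.numeric(spec$slopes))
      y <- stats::runif(n) < stats::plogis(lp)
      if (oc == "drugs_3m") y <- y & ever_drugs
      profiles[[oc]] <- y
    }
    profiles
  })
}

#' Monte Carlo parameter-recovery experiment
#'
#' Repeatedly simulates choice data from the configured truth, fits the
#' requested estimator, and summarises recovery of every level utility
#' (including the implied reference levels) and the opt-out constant:
#' replicate mean, bias, empirical SD over replicates, and the Monte Carlo
#' standard error of the mean. Non-convergent replicates are excluded and
#' counted. Deterministic given the seed schedule (`seed + replicate`).
#'
#' @param config a [generator_config()].
#' @param design a [choice_design()].
#' @param n_replicates number of simulated datasets (>= 2).
#' @param estimator `"mnl"` or `"mmnl"`.
#' @param seed base seed; replicate r uses `seed + r`.
#' @param n_respondents override of the configured respondent count.
#' @param estimator_args extra arguments passed to the fitting function
#'   (e.g. `n_draws` for the MMNL estimator).
#' @return object of class `recovery_report`: data frame `summary`
#'   (quantity, truth, mean, bias, empirical_se, mc_se), matrix
#'   `estimates` (replicates x quantities), counts of converged and
#'   excluded replicates, and the seed schedule.
#' @export
recovery_experiment <- function(config, design, n_replicates = 50L,
                                estimator = c("mnl", "mmnl"), seed = 1L,
                                n_respondents = NULL, estimator_args = list()) {
  estimator <- match.arg(estimator)
  if (n_replicates < 2L) stop_dce("n_replicates must be >= 2")
  truth_lu <- level_utilities(config$beta, config$attributes)
  qnames <- c(paste(truth_lu$attribute, truth_lu$level, sep = " | "))
  truth <- stats::setNames(truth_lu$utility, qnames)
  ests <- matrix(NA_real_, n_replicates, length(truth),
                 dimnames = list(NULL, qnames))
  excluded <- 0L
  for (i in seq_len(n_replicates)) {
    ds <- generate_choices(config, design, seed = seed + i,
                           n_respondents = n_respondents)
    fit <- tryCatch(
      do.call(if (estimator == "mnl") fit_mnl else fit_mmnl,
              c(list(ds), estimator_args)),
      error = function(e) NULL)
    if (is.null(fit) || !isTRUE(fit$converged)) { excluded <- excluded + 1L; next }
    lu <- level_utilities(fit)
    ests[i, ] <- lu$utility[match(qnames, paste(lu$attribute, lu$level,
                                                sep = " | "))]
  }
  ok <- stats::complete.cases(ests)
  m <- colMeans(ests[ok, , drop = FALSE])
  esd <- apply(ests[ok, , drop = FALSE], 2L, stats::sd)
  summary <- data.frame(
    quantity = qnames,
    truth = unname(truth),
    mean = unname(m),
    bias = unname(m - truth),
    empirical_se = unname(esd),
    mc_se = unname(esd / sqrt(sum(ok))),
    stringsAsFactors = FALSE, row.names = NULL
  )
  structure(list(summary = summary, estimates = ests,
                 n_replicates = n_replicates, n_converged = sum(ok),
                 n_excluded = excluded, estimator = estimator, seed = seed),
            class = "recovery_report")
}

#' @export
print.recovery_report <- function(x, ...) {
  cat(sprintf("<recovery_report: %s, %d/%d replicates converged>\n",
              toupper(x$estimator), x$n_converged, x$n_replicates))
  print(transform(x$summary,
                  truth = round(truth, 3), mean = round(mean, 3),
                  bias = round(bias, 4), empirical_se = round(empirical_se, 4),
                  mc_se = round(mc_se, 4)), row.names = FALSE)
  invisible(x)
}
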