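# Pipeline orchestration: design -> simulate/ingest -> fit -> WTA ->
# survey scoring -> risk regressions -> reports, with per-stage logging
# and deterministic outputs (config hash + seed stamped on every artifact).

#' Recode an effects-coded attribute as continuous
#'
#' Replaces an attribute's contrast columns in a coded dataset by a single
#' numeric column holding the level's configured value (e.g. money in
#' GMD, optionally rescaled for optimiser conditioning). Level assignments
#' are recovered from the contrast pattern; opt-out rows keep 0.
#'
#' @param dataset a [choice_dataset()] carrying its attribute list.
#' @param attribute name of the attribute to recode (default `"money"`).
#' @param scale divisor applied to the numeric values (1 keeps GMD units).
#' @return a new [choice_dataset()] with the attribute coded continuous.
#' @export
recode_continuous <- function(dataset, attribute = "money", scale = 1) {
  attributes <- attr(dataset, "attributes")
  if (is.null(attributes)) stop_dce("dataset carries no attribute specification")
  nm <- vapply(attributes, `[[`, character(1), "name")
  i <- match(attribute, nm)
  if (is.na(i)) stop_dce("unknown attribute '%s'", attribute)
  a <- attributes[[i]]
  if (is.null(a$numeric_values))
    stop_dce("attribute '%s' has no numeric level values", attribute)
  L <- n_levels(a)
  cols <- paste0(a$name, ".", seq_len(L - 1L))
  M <- as.matrix(as.data.frame(dataset)[cols])
  lev <- integer(nrow(M))
  is_ref <- rowSums(M == -1) == (L - 1L)
  lev[is_ref] <- L
  for (k in seq_len(L - 1L)) lev[!is_ref & M[, k] == 1] <- k
  zero <- rowSums(M != 0) == 0
  lev[zero] <- 1L   # placeholder; value forced to 0 below
  value <- ifelse(zero, 0, a$numeric_values[lev] / scale)
  new_attr <- attributes
  new_attr[[i]] <- attribute_spec(a$name, a$levels, coding = "continuous",
                                  numeric_values = a$numeric_values / scale,
                                  units = a$units)
  df <- as.data.frame(dataset)
  df <- df[, setdiff(names(df), cols)]
  df[[a$name]] <- value
  cat_new <- coding_catalogue(new_attr)
  df <- df[, c("respondent_id", "task_id", "alt_id", "chosen", cat_new$column)]
  choice_dataset(df, cat_new, new_attr)
}

#' Load long-format choice data
#'
#' Thin alias of [read_choice_data()] under the pipeline's stage name.
#' @inheritParams read_choice_data
#' @return a [choice_dataset()].
#' @export
load_choice_data <- function(path, design_config = NULL) {
  read_choice_data(path, design_config)
}

pipeline_defaults <- function() {
  list(
    stages = list(design = TRUE, simulate = TRUE, mnl = TRUE, mmnl = FALSE,
                  wta = TRUE, survey = TRUE, correlates = TRUE,
                  recover = FALSE),
    seed = 1L,
    output_dir = "dcekit_output",
    generator_config = NULL,       # path or NULL for packaged defaults
    attributes_config = NULL,
    choice_data = NULL,            # path to observed data; NULL -> simulate
    survey_data = NULL,
    design = list(priors = "zero", n_restarts = 2L, n_tasks = NULL),
    estimation = list(tolerance = 1e-6, n_draws = 1000L),
    wta = list(n_sim_draws = 10000L, level = 0.95),
    recover = list(n_replicates = 50L, estimator = "mnl")
  )
}

merge_config <- function(defaults, user) {
  for (nm in names(user)) {
    if (is.list(defaults[[nm]]) && is.list(user[[nm]]))
      defaults[[nm]] <- merge_config(defaults[[nm]], user[[nm]])
    else defaults[[nm]] <- user[[nm]]
  }
  defaults
}

config_hash <- function(config) {
  config$output_dir <- NULL   # where results land cannot change their values
  tmp <- tempfile(fileext = ".json")
  on.exit(unlink(tmp))
  jsonlite::write_json(config, tmp, auto_unbox = TRUE, digits = NA,
                       force = TRUE)
  unname(tools::md5sum(tmp))
}

#' Run the full analysis pipeline
#'
#' Orchestrates the stages behind one call: build a D-efficient design,
#' simulate (or load) choice data, fit the MNL and optionally the MMNL,
#' compute willingness-to-accept from a continuous-money refit, simulate
#' (or load) and score the survey, fit the five risk-behaviour
#' regressions, and optionally run a parameter-recovery experiment. Every
#' artifact is written under `output_dir` and stamped with the config hash
#' and seed; per-stage timing and sizes go to `run_log.txt` and stderr.
#' Any stage failure halts with the stage named; artifacts already
#' written are preserved.
#'
#' @param config named list overriding the defaults (stage toggles under
#'   `stages`, `seed`, `output_dir`, paths and per-stage options), or a
#'   path to a YAML file of the same shape.
#' @param quiet suppress stderr logging.
#' @return named list of produced artifact paths plus the key fitted
#'   objects, invisibly.
#' @export
run_pipeline <- function(config = list(), quiet = FALSE) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  cfg <- merge_config(pipeline_defaults(), config)
  seed <- as.integer(cfg$seed)
  dir.create(cfg$output_dir, recursive = TRUE, showWarnings = FALSE)
  log_path <- file.path(cfg$output_dir, "run_log.txt")
  log_con <- file(log_path, open = "wt")
  on.exit(close(log_con))
  hash <- config_hash(cfg)
  t0 <- Sys.time()
  say <- function(fmt, ...) {
    msg <- sprintf("[%.1fs] %s", as.numeric(Sys.time() - t0, units = "secs"),
                   sprintf(fmt, ...))
    writeLines(msg, log_con)
    if (!quiet) message(msg)
  }
  stage <- function(name, enabled, expr) {
    if (!isTRUE(enabled)) { say("stage %s: skipped", name); return(NULL) }
    say("stage %s: start", name)
    res <- tryCatch(expr, error = function(e)
      stop_dce("pipeline stage '%s' failed: %s", name, conditionMessage(e)))
    say("stage %s: done", name)
    res
  }
  artifacts <- list()
  results <- list(config_hash = hash, seed = seed)
  say("run config hash %s, seed %d", hash, seed)

  gen <- generator_config(cfg$generator_config, cfg$attributes_config)
  n_tasks <- cfg$design$n_tasks %||% gen$design_settings$n_tasks %||% 8L
  n_alts <- gen$design_settings$n_profile_alternatives %||% 2L

  design <- stage("design", cfg$stages$design, {
    priors <- if (identical(cfg$design$priors, "truth")) gen$beta
              else numeric(length(gen$beta))
    d <- search_efficient_design(gen$attributes, priors, n_tasks = n_tasks,
                                 n_alternatives = n_alts, seed = seed,
                                 n_restarts = cfg$design$n_restarts)
    artifacts$design <- file.path(cfg$output_dir, "design.json")
    design_to_json(d, artifacts$design)
    artifacts$questionnaire <- file.path(cfg$output_dir, "questionnaire.tsv")
    write_questionnaire(d, artifacts$questionnaire)
    say("  D-error %.6g over %d tasks", d$meta$d_error, d$n_tasks)
    d
  })

  dataset <- stage("simulate", cfg$stages$simulate || !is.null(cfg$choice_data), {
    if (!is.null(cfg$choice_data)) {
      say("  loading %s", cfg$choice_data)
      read_choice_data(cfg$choice_data, list(attributes = gen$attributes))
    } else {
      if (is.null(design)) stop_dce("simulation needs the design stage")
      ds <- generate_choices(gen, design, seed = seed)
      artifacts$choices <- file.path(cfg$output_dir, "choices.tsv")
      write_choice_data(ds, artifacts$choices)
      say("  %d respondents x %d tasks", length(unique(ds$respondent_id)),
          n_tasks)
      ds
    }
  })

  mnl <- stage("mnl", cfg$stages$mnl && !is.null(dataset), {
    fit <- fit_mnl(dataset, tolerance = cfg$estimation$tolerance)
    if (!fit$converged) stop_dce("MNL estimation did not converge")
    artifacts$mnl <- file.path(cfg$output_dir, "estimation_mnl.json")
    fit_to_json(fit, artifacts$mnl)
    say("  LL %.3f, gradient norm %.2e", fit$log_likelihood, fit$gradient_norm)
    fit
  })

  mmnl <- stage("mmnl", cfg$stages$mmnl && !is.null(dataset), {
    fit <- fit_mmnl(dataset, n_draws = cfg$estimation$n_draws, seed = seed)
    fit$seed <- seed
    artifacts$mmnl <- file.path(cfg$output_dir, "estimation_mmnl.json")
    fit_to_json(fit, artifacts$mmnl)
    say("  simulated LL %.3f with %d draws", fit$log_likelihood, fit$n_draws)
    fit
  })

  wta_res <- stage("wta", cfg$stages$wta && !is.null(dataset), {
    ds_cont <- recode_continuous(dataset, "money")
    fit <- fit_mnl(ds_cont, tolerance = cfg$estimation$tolerance)
    contrasts <- list(
      condom_never_vs_always = list(attribute = "condom_use",
                                    from = "Condom used every time",
                                    to = "Condom never used"),
      # utility change of entering a relationship at all = losing the
      # opt-out, so the contrast is minus the opt-out constant
      tourist_relationship = list(coefficient = "opt_out", weight = -1)
    )
    est <- lapply(contrasts, function(ct)
      wta(fit, ct, money_key = "money",
          n_sim_draws = cfg$wta$n_sim_draws, seed = seed,
          level = cfg$wta$level))
    artifacts$wta <- file.path(cfg$output_dir, "wta.json")
    wta_to_json(est, artifacts$wta)
    for (nm in names(est))
      say("  WTA %s = %.0f GMD", nm, est[[nm]]$point)
    est
  })

  survey <- stage("survey", cfg$stages$survey || !is.null(cfg$survey_data), {
    prof <- if (!is.null(cfg$survey_data)) read_survey_data(cfg$survey_data)
            else generate_survey(gen, seed = seed)
    artifacts$survey <- file.path(cfg$output_dir, "survey_scored.tsv")
    write_survey_data(prof, artifacts$survey)
    say("  %d respondents scored", nrow(prof))
    prof
  })

  correlates <- stage("correlates", cfg$stages$correlates && !is.null(survey), {
    models <- fit_risk_models(survey)
    artifacts$risk_json <- file.path(cfg$output_dir, "risk_tables.json")
    risk_tables_to_json(models, artifacts$risk_json)
    artifacts$risk_table <- file.path(cfg$output_dir, "risk_table.tsv")
    write_risk_table(models, artifacts$risk_table)
    for (m in models)
      say("  %s: n=%d, McFadden R2=%.3f%s", m$outcome, m$n_observations,
          m$pseudo_r2,
          if (length(m$omitted)) paste0(", omitted: ",
                                        paste(names(m$omitted), collapse = ", "))
          else "")
    models
  })

  recovery <- stage("recover", cfg$stages$recover && !is.null(design), {
    rep <- recovery_experiment(gen, design,
                               n_replicates = cfg$recover$n_replicates,
                               estimator = cfg$recover$estimator, seed = seed)
    artifacts$recovery <- file.path(cfg$output_dir, "recovery.json")
    jsonlite::write_json(list(summary = rep$summary,
                              n_converged = rep$n_converged,
                              n_excluded = rep$n_excluded,
                              estimator = rep$estimator, seed = seed,
                              config_hash = hash),
                         artifacts$recovery, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE)
    rep
  })

  manifest <- list(config_hash = hash, seed = seed,
                   created = format(t0, "%Y-%m-%dT%H:%M:%S"),
                   artifacts = artifacts)
  manifest_path <- file.path(cfg$output_dir, "manifest.json")
  jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  say("pipeline complete: %d artifacts", length(artifacts))
  invisible(list(artifacts = c(artifacts, manifest = manifest_path),
                 design = design, dataset = dataset, mnl = mnl, mmnl = mmnl,
                 wta = wta_res, survey = survey, correlates = correlates,
                 recovery = recovery, config_hash = hash, seed = seed))
}
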