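#' Construct a choice design
#'
#' A design assigns, for every task and every non-opt-out alternative, one
#' level of each attribute. The study configuration is 8 tasks of two
#' unlabelled profiles plus a "neither" opt-out; the opt-out carries no
#' attribute profile and is coded as a row of zeros with a 1 in the opt-out
#' constant column.
#'
#' @param attributes list of [attribute_spec()].
#' @param profiles integer array `[n_tasks, n_alternatives, n_attributes]`
#'   of level indices.
#' @param has_opt_out append an opt-out alternative to every task?
#' @return object of class `choice_design`.
#' @export
choice_design <- function(attributes, profiles, has_opt_out = TRUE) {
  check_attributes(attributes)
  if (length(dim(profiles)) != 3L)
    stop_dce("profiles must be a 3-d array [task, alternative, attribute]")
  if (dim(profiles)[3] != length(attributes))
    stop_dce("profiles third dimension (%d) must match attribute count (%d)",
             dim(profiles)[3], length(attributes))
  storage.mode(profiles) <- "integer"
  for (i in seq_along(attributes)) {
    v <- profiles[, , i]
    if (any(is.na(v)) || any(v < 1L) || any(v > n_levels(attributes[[i]])))
      stop_dce("attribute '%s': level index out of range in profiles",
               attributes[[i]]$name)
  }
  structure(
    list(attributes = attributes, profiles = profiles,
         n_tasks = dim(profiles)[1], n_profile_alts = dim(profiles)[2],
         has_opt_out = isTRUE(has_opt_out), meta = list()),
    class = "choice_design"
  )
}

#' @export
print.choice_design <- function(x, ...) {
  cat(sprintf("<choice_design: %d tasks x (%d profiles%s), %d attributes>\n",
              x$n_tasks, x$n_profile_alts,
              if (x$has_opt_out) " + opt-out" else "", length(x$attributes)))
  if (!is.null(x$meta$d_error))
    cat(sprintf("  D-error %.6g (seed %s, %s)\n", x$meta$d_error,
                x$meta$seed %||% "?", x$meta$method %||% "given"))
  invisible(x)
}

# Coded matrices, one per task: (n_profile_alts [+1]) x K.
coded_task_matrices <- function(design) {
  A <- design$attributes
  flat <- matrix(aperm(design$profiles, c(2, 1, 3)),
                 nrow = design$n_tasks * design$n_profile_alts,
                 ncol = length(A))
  coded <- code_profiles(flat, A, opt_out = TRUE)
  oo <- opt_out_row(A)
  lapply(seq_len(design$n_tasks), function(t) {
    idx <- (t - 1L) * design$n_profile_alts + seq_len(design$n_profile_alts)
    m <- coded[idx, , drop = FALSE]
    if (design$has_opt_out) m <- rbind(m, oo)
    rownames(m) <- NULL
    m
  })
}

# Fisher information contribution of one task at coefficients beta:
# sum_j p_j (x_j - xbar)(x_j - xbar)' with xbar = sum_k p_k x_k.
task_information <- function(X, beta) {
  p <- softmax(as.vector(X %*% beta))
  xbar <- colSums(p * X)
  crossprod(X * sqrt(p)) - tcrossprod(xbar)
}

d_error_from_info <- function(info, K) {
  ld <- determinant(info, logarithm = TRUE)
  if (ld$sign <= 0 || !is.finite(ld$modulus) || ld$modulus < -500)
    return(structure(Inf, singular = TRUE))
  structure(exp(-ld$modulus / K), singular = FALSE)
}

#' D-error of a design at prior coefficients
#'
#' The D-error is `det(I(beta))^(-1/K)` where `I` is the multinomial-logit
#' Fisher information of the coded design evaluated at the prior
#' coefficient vector and `K` the number of coded parameters. Lower is
#' better; a design whose information matrix is singular (e.g. both profile
#' alternatives identical in every task) has undefined efficiency and is
#' reported as `Inf` with attribute `singular = TRUE` rather than an error.
#'
#' @param design a [choice_design()].
#' @param priors numeric vector of prior coefficients, length equal to the
#'   coded column count (effects contrasts + continuous columns + opt-out
#'   constant when present).
#' @return positive scalar; `Inf` (with `attr(, "singular")`) when the
#'   information matrix is singular.
#' @export
d_error <- function(design, priors) {
  stopifnot(inherits(design, "choice_design"))
  if (design$n_tasks < 1L) stop_dce("design has no tasks")
  Xs <- coded_task_matrices(design)
  K <- ncol(Xs[[1]])
  priors <- as.numeric(priors)
  if (length(priors) != K)
    stop_dce("priors length %d does not match %d coded columns",
             length(priors), K)
  info <- Reduce(`+`, lapply(Xs, task_information, beta = priors))
  d_error_from_info(info, K)
}

#' Seeded balanced starting design
#'
#' Approximates an orthogonal pilot design by a seeded random
#' level-balanced design: within each attribute, levels are spread as
#' evenly as possible over the task-by-alternative slots, then shuffled
#' independently per attribute. Used both as the pilot instrument stand-in
#' and as the restart points of [search_efficient_design()]; the
#' construction method is flagged in the design metadata.
#'
#' @inheritParams search_efficient_design
#' @return a [choice_design()] with `meta$method = "random_balanced"`.
#' @export
pilot_design <- function(attributes, n_tasks = 8L, n_alternatives = 2L,
                         has_opt_out = TRUE, seed = 1L) {
  check_attributes(attributes)
  slots <- n_tasks * n_alternatives
  prof <- local_seed(seed, {
    cols <- lapply(attributes, function(a) {
      v <- rep_len(seq_len(n_levels(a)), slots)
      sample(v)
    })
    array(unlist(cols), dim = c(n_alternatives, n_tasks, length(attributes)))
  })
  d <- choice_design(attributes, aperm(prof, c(2, 1, 3)),
                     has_opt_out = has_opt_out)
  d$meta$method <- "random_balanced"
  d$meta$seed <- seed
  d
}

#' Search for a D-efficient design by coordinate exchange
#'
#' Starting from seeded random balanced designs, repeatedly sweeps over
#' every (task, alternative) slot and exchanges the profile for the
#' candidate from the full factorial that most reduces the D-error at the
#' prior coefficients, accepting only strict improvements, until a full
#' sweep makes no change. The best design over `n_restarts` restarts is
#' returned. The trajectory of accepted D-errors is monotone non-increasing
#' by construction and is stored in the design metadata.
#'
#' @param attributes list of [attribute_spec()].
#' @param priors prior coefficient vector on the coded scale (effects
#'   contrasts + continuous columns + opt-out constant); zeros give the
#'   utility-neutral design.
#' @param n_tasks number of choice tasks.
#' @param n_alternatives number of profile (non-opt-out) alternatives.
#' @param has_opt_out include a "neither" opt-out in every task?
#' @param seed integer seed making the search deterministic.
#' @param n_restarts number of random restarts.
#' @param candidates optional integer matrix of candidate profiles (rows =
#'   profiles, columns = attributes); defaults to the full factorial.
#' @param max_sweeps cap on exchange sweeps per restart.
#' @return a [choice_design()] with `meta` fields `d_error`, `trajectory`,
#'   `seed`, `method`.
#' @export
search_efficient_design <- function(attributes, priors, n_tasks = 8L,
                                    n_alternatives = 2L, has_opt_out = TRUE,
                                    seed = 1L, n_restarts = 2L,
                                    candidates = NULL, max_sweeps = 20L) {
  check_attributes(attributes)
  if (n_tasks < 1L) stop_dce("n_tasks must be >= 1")
  full_space <- is.null(candidates)
  if (full_space) candidates <- full_factorial(attributes)
  if (nrow(candidates) == 0L) stop_dce("empty candidate profile space")
  C <- code_profiles(candidates, attributes, opt_out = TRUE)
  K <- ncol(C)
  priors <- as.numeric(priors)
  if (length(priors) != K)
    stop_dce("priors length %d does not match %d coded columns",
             length(priors), K)
  oo <- opt_out_row(attributes)
  nC <- nrow(candidates)
  n_extra <- if (has_opt_out) 1L else 0L

  task_info_idx <- function(idx) {
    X <- C[idx, , drop = FALSE]
    if (has_opt_out) X <- rbind(X, oo)
    task_information(X, priors)
  }

  best <- NULL
  best_d <- Inf
  for (r in seq_len(n_restarts)) {
    if (full_space) {
      start <- pilot_design(attributes, n_tasks, n_alternatives,
                            has_opt_out, seed = seed + (r - 1L))
      key <- apply(candidates, 1L, paste, collapse = ".")
      assign_idx <- matrix(0L, n_tasks, n_alternatives)
      for (t in seq_len(n_tasks)) for (a in seq_len(n_alternatives)) {
        k <- paste(start$profiles[t, a, ], collapse = ".")
        assign_idx[t, a] <- match(k, key)
      }
    } else {
      assign_idx <- local_seed(seed + (r - 1L), {
        matrix(sample.int(nC, n_tasks * n_alternatives, replace = TRUE),
               n_tasks, n_alternatives)
      })
    }

    infos <- lapply(seq_len(n_tasks), function(t) task_info_idx(assign_idx[t, ]))
    info <- Reduce(`+`, infos)
    d_cur <- as.numeric(d_error_from_info(info, K))
    traj <- d_cur
    for (sweep in seq_len(max_sweeps)) {
      changed <- FALSE
      for (t in seq_len(n_tasks)) for (a in seq_len(n_alternatives)) {
        base_info <- info - infos[[t]]
        idx <- assign_idx[t, ]
        best_c <- idx[a]; best_dc <- d_cur; best_M <- infos[[t]]
        for (cand in seq_len(nC)) {
          if (cand == idx[a]) next
          idx2 <- idx; idx2[a] <- cand
          M <- task_info_idx(idx2)
          d_new <- as.numeric(d_error_from_info(base_info + M, K))
          if (d_new < best_dc - 1e-12) {
            best_dc <- d_new; best_c <- cand; best_M <- M
          }
        }
        if (best_c != idx[a]) {
          assign_idx[t, a] <- best_c
          infos[[t]] <- best_M
          info <- base_info + best_M
          d_cur <- best_dc
          traj <- c(traj, d_cur)
          changed <- TRUE
        }
      }
      if (!changed) break
    }
    if (d_cur < best_d) {
      prof <- array(0L, dim = c(n_tasks, n_alternatives, length(attributes)))
      for (t in seq_len(n_tasks)) for (a in seq_len(n_alternatives))
        prof[t, a, ] <- candidates[assign_idx[t, a], ]
      best <- choice_design(attributes, prof, has_opt_out = has_opt_out)
      best$meta <- list(d_error = d_cur, trajectory = traj, seed = seed,
                        restart = r, method = "coordinate_exchange",
                        start_method = "random_balanced")
      best_d <- d_cur
    }
  }
  if (!is.finite(best_d))
    stop_dce("all candidate designs are singular at the supplied priors")
  best
}

#' Export a design
#'
#' `design_to_json()` writes the machine-readable design (attributes,
#' profiles, metadata); `write_questionnaire()` writes a human-readable
#' delimited questionnaire, one row per task x alternative with level
#' labels.
#'
#' @param design a [choice_design()].
#' @param path output file path.
#' @return the path, invisibly.
#' @export
design_to_json <- function(design, path) {
  A <- design$attributes
  obj <- list(
    attributes = lapply(A, function(a)
      list(name = a$name, levels = a$levels, coding = a$coding,
           numeric_values = a$numeric_values, units = a$units)),
    n_tasks = design$n_tasks,
    n_profile_alternatives = design$n_profile_alts,
    has_opt_out = design$has_opt_out,
    profiles = design$profiles,
    meta = design$meta[setdiff(names(design$meta), "trajectory")]
  )
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' @rdname design_to_json
#' @param sep field separator for the questionnaire file.
#' @export
write_questionnaire <- function(design, path, sep = "\t") {
  A <- design$attributes
  rows <- list()
  for (t in seq_len(design$n_tasks)) {
    for (a in seq_len(design$n_profile_alts)) {
      labs <- vapply(seq_along(A), function(i)
        A[[i]]$levels[design$profiles[t, a, i]], character(1))
      rows[[length(rows) + 1L]] <- c(task = t, alternative = a, labs)
    }
    if (design$has_opt_out)
      rows[[length(rows) + 1L]] <- c(task = t, alternative = design$n_profile_alts + 1L,
                                     rep("Neither", length(A)))
  }
  df <- as.data.frame(do.call(rbind, rows), stringsAsFactors = FALSE)
  names(df) <- c("task", "alternative", vapply(A, `[[`, character(1), "name"))
  utils::write.table(df, path, sep = sep, row.names = FALSE, quote = TRUE)
  invisible(path)
}
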