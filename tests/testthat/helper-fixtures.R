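# Shared fixtures: tiny attribute sets, toy datasets and an oracle or two.

study_attributes <- function() {
  generator_config()$attributes
}

binary_attribute <- function(name = "x", levels = c("a", "b")) {
  attribute_spec(name, levels)
}

toy_attributes <- function() {
  list(attribute_spec("risk", c("low", "high")),
       attribute_spec("pay", c("none", "some", "lots")))
}

# Hand-rolled choice data: one respondent per task unless stated, J
# alternatives, coded columns supplied directly.
make_dataset <- function(X, chosen, J, n_resp = NULL, catalogue = NULL,
                         attributes = NULL) {
  n <- nrow(X)
  n_tasks <- n / J
  if (is.null(n_resp)) n_resp <- n_tasks
  tasks_per_resp <- n_tasks / n_resp
  df <- data.frame(
    respondent_id = rep(seq_len(n_resp), each = tasks_per_resp * J),
    task_id = rep(rep(seq_len(tasks_per_resp), each = J), times = n_resp),
    alt_id = rep(seq_len(J), times = n_tasks),
    chosen = chosen
  )
  df <- cbind(df, as.data.frame(X, check.names = FALSE))
  choice_dataset(df, catalogue, attributes)
}

# Independent brute-force MNL Fisher information: explicit loops, no reuse
# of package internals.
brute_force_information <- function(task_list, beta) {
  K <- length(beta)
  info <- matrix(0, K, K)
  for (X in task_list) {
    u <- numeric(nrow(X))
    for (j in seq_len(nrow(X))) u[j] <- sum(X[j, ] * beta)
    p <- exp(u) / sum(exp(u))
    xbar <- numeric(K)
    for (j in seq_len(nrow(X))) xbar <- xbar + p[j] * X[j, ]
    for (j in seq_len(nrow(X))) {
      d <- X[j, ] - xbar
      info <- info + p[j] * outer(d, d)
    }
  }
  info
}

# 1-D star discrepancy of points in (0,1).
star_discrepancy <- function(x) {
  x <- sort(x)
  n <- length(x)
  i <- seq_len(n)
  max(pmax(abs(i / n - x), abs(x - (i - 1) / n)))
}

expect_dce_error <- function(expr, pattern = NULL) {
  expect_error(expr, regexp = pattern, class = "dcekit_error")
}
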