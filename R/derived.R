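# Summaries derived from an intensity matrix: sojourn times, length of
# stay, prevalence projection, and the projection validation rule.

#' Mean sojourn time per state
#'
#' The expected duration of a single uninterrupted stay in state r is
#' `-1 / q_rr`, the mean of the exponential holding time with rate equal to
#' the total exit intensity. A state with no exit intensity is absorbing
#' and gets `Inf`.
#'
#' @param Q 3x3 intensity matrix.
#' @return Named numeric vector of years (one per state).
#' @examples
#' mean_sojourn(reference_intensities("all"))
#' @export
mean_sojourn <- function(Q) {
  check_q(Q)
  d <- diag(Q)
  out <- ifelse(d < 0, -1 / d, Inf)
  names(out) <- STATE_NAMES
  out
}

#' Total length of stay in each state over a horizon
#'
#' The expected cumulative time spent in each state over `[0, T]`, starting
#' from `start_state`, is the integral of the transition probabilities:
#' `L_s = integral_0^T P_{start,s}(u) du`. It is computed exactly through
#' the augmented block-matrix exponential `expm(T * [[Q, I], [0, 0]])`,
#' whose upper-right block equals `integral_0^T expm(Qu) du` -- no
#' quadrature tolerance is involved, and the entries sum to `T` by
#' construction.
#'
#' @param Q 3x3 intensity matrix.
#' @param start_state State occupied at time 0 (1, 2 or 3).
#' @param horizon T in years (> 0).
#' @return Named numeric vector of years per state, summing to `horizon`.
#' @export
total_length_of_stay <- function(Q, start_state = 1L, horizon) {
  check_q(Q)
  stopifnot(start_state %in% 1:3, is.finite(horizon), horizon > 0)
  A <- rbind(cbind(Q, diag(3)), matrix(0, 3, 6))
  E <- as.matrix(Matrix::expm(A * horizon))
  out <- E[start_state, 4:6]
  names(out) <- STATE_NAMES
  out
}

#' Project state prevalence forward from an initial distribution
#'
#' `init' P(t)`: mixes the rows of the transition probability matrix with
#' the baseline state distribution, giving the model-projected prevalence
#' of each state after `t` years.
#'
#' @param init_dist Length-3 probability vector (sums to 1).
#' @param Q 3x3 intensity matrix.
#' @param t Horizon in years.
#' @return Named length-3 probability vector.
#' @export
project_prevalence <- function(init_dist, Q, t) {
  stopifnot(length(init_dist) == 3L)
  if (any(init_dist < 0)) stop("initial distribution has negative entries")
  if (abs(sum(init_dist) - 1) > 1e-6)
    stop("initial distribution must sum to 1")
  P <- transition_probability(Q, t)
  out <- as.vector(init_dist %*% P)
  names(out) <- STATE_NAMES
  out
}

#' Probability of leaving a state within t years
#'
#' `1 - P_ss(t)`: the chance that a child starting in `state` occupies a
#' different state at time `t` (regardless of the path in between).
#'
#' @param Q 3x3 intensity matrix.
#' @param state Starting state (1, 2 or 3).
#' @param t Horizon in years.
#' @return Probability in `[0, 1]`.
#' @export
leave_probability <- function(Q, state, t) {
  stopifnot(state %in% 1:3)
  P <- transition_probability(Q, t)
  unname(1 - P[state, state])
}

#' Validate projected prevalence against observed values
#'
#' A projection is accepted when it falls inside the 95% CI of the observed
#' prevalence, or when the absolute difference from the observed value is
#' less than 1% *of the predicted value* (a relative criterion); otherwise
#' it is flagged as a discrepancy.
#'
#' @param predicted Model-projected prevalence (same units as observed,
#'   e.g. percent).
#' @param observed Observed prevalence.
#' @param lower,upper 95% CI bounds of the observed prevalence.
#' @return data.frame with `predicted`, `observed`, `lower`, `upper`,
#'   `valid` (logical) and `reason` (`"within_ci"`, `"within_1pct"`,
#'   `"flagged"`); vectorized over its arguments.
#' @export
validate_projection <- function(predicted, observed, lower, upper) {
  n <- length(predicted)
  stopifnot(length(observed) == n, length(lower) == n, length(upper) == n)
  if (any(lower > upper)) stop("inverted confidence interval (lower > upper)")
  in_ci <- predicted >= lower & predicted <= upper
  close <- abs(predicted - observed) < 0.01 * predicted
  data.frame(predicted = predicted, observed = observed,
             lower = lower, upper = upper,
             valid = in_ci | close,
             reason = ifelse(in_ci, "within_ci",
                             ifelse(close, "within_1pct", "flagged")))
}

#' Internal: Wald CI of a smooth function of the fitted parameters
#'
#' Delta method: gradient of `fun` (mapping the fitted parameter vector,
#' log intensities first, to a numeric vector) at the MLE, numerically
#' differentiated; variance `J V J'`. Bootstrap: parametric draws from the
#' asymptotic normal of the parameters, empirical quantiles.
#' @noRd
fit_interval <- function(fit, fun, method = c("delta", "bootstrap"),
                         level = 0.95, B = 1000L) {
  stopifnot(inherits(fit, "markov3_fit"))
  method <- match.arg(method)
  theta <- fit$theta
  est <- fun(theta)
  z <- stats::qnorm(1 - (1 - level) / 2)
  if (method == "delta") {
    J <- pracma::jacobian(fun, theta)
    v <- diag(J %*% fit$vcov %*% t(J))
    se <- sqrt(pmax(v, 0))
    lo <- est - z * se; hi <- est + z * se
  } else {
    draws <- MASS::mvrnorm(B, theta, fit$vcov)
    sims <- t(apply(draws, 1L, fun))
    if (length(est) == 1L) sims <- matrix(sims, ncol = 1L)
    lo <- apply(sims, 2L, stats::quantile, probs = (1 - level) / 2)
    hi <- apply(sims, 2L, stats::quantile, probs = 1 - (1 - level) / 2)
  }
  data.frame(estimate = est, lower = lo, upper = hi)
}

#' Internal: rebuild the baseline Q from a fitted parameter vector
#' @noRd
theta_to_q <- function(theta) {
  q <- exp(theta[1:4])
  intensity_matrix(q[1L], q[2L], q[3L], q[4L])
}

#' Derived transition summaries at one or more horizons
#'
#' Bundles, for an intensity matrix or a fitted model, the quantities a
#' multistate weight-status analysis reports: transition probabilities
#' P(t) at each horizon, total length of stay in each state from each
#' starting state, mean sojourn times, and (optionally) a prevalence
#' projection from a baseline distribution. When a `markov3_fit` is given,
#' 95% confidence intervals are attached by the delta method on the
#' log-intensity scale (or by parametric bootstrap).
#'
#' @param x A 3x3 intensity matrix or a `markov3_fit`.
#' @param horizons Numeric vector of horizons in years.
#' @param init Optional baseline state distribution for prevalence
#'   projection.
#' @param ci_method `"delta"` or `"bootstrap"` (fit input only).
#' @param B Bootstrap draws when `ci_method = "bootstrap"`.
#' @return Object of class `transition_summary`: data.frames
#'   `probabilities` (`horizon`, `from`, `to`, `estimate` [, `lower`,
#'   `upper`]), `length_of_stay`, `sojourn`, and `prevalence` (if `init`
#'   given).
#' @export
transition_summary <- function(x, horizons = c(1, 5), init = NULL,
                               ci_method = c("delta", "bootstrap"),
                               B = 1000L) {
  ci_method <- match.arg(ci_method)
  fit <- NULL
  if (inherits(x, "markov3_fit")) {
    fit <- x
    Q <- fit$qmatrix
  } else {
    Q <- x
    check_q(Q)
  }
  grid <- expand.grid(to = 1:3, from = 1:3, horizon = horizons)[, 3:1]

  with_ci <- function(fun, est_len) {
    if (is.null(fit)) data.frame(estimate = fun(log_q = NULL))
    else fit_interval(fit, fun, method = ci_method, B = B)
  }

  p_fun <- function(theta = NULL, log_q = NULL) {
    Qc <- if (is.null(theta)) Q else theta_to_q(theta)
    unlist(lapply(horizons, function(h) {
      P <- transition_probability(Qc, h)
      as.vector(t(P))  # row-major: from 1 (to 1,2,3), from 2, ...
    }))
  }
  probs <- cbind(grid, with_ci(p_fun))
  probs$from <- STATE_NAMES[probs$from]
  probs$to <- STATE_NAMES[probs$to]

  los_grid <- expand.grid(state = 1:3, from = 1:3, horizon = horizons)[, 3:1]
  los_fun <- function(theta = NULL, log_q = NULL) {
    Qc <- if (is.null(theta)) Q else theta_to_q(theta)
    unlist(lapply(horizons, function(h)
      unlist(lapply(1:3, function(s0) total_length_of_stay(Qc, s0, h)))))
  }
  los <- cbind(los_grid, with_ci(los_fun))
  los$from <- STATE_NAMES[los$from]
  los$state <- STATE_NAMES[los$state]

  soj_fun <- function(theta = NULL, log_q = NULL) {
    Qc <- if (is.null(theta)) Q else theta_to_q(theta)
    mean_sojourn(Qc)
  }
  soj <- cbind(data.frame(state = STATE_NAMES), with_ci(soj_fun))

  prev <- NULL
  if (!is.null(init)) {
    prev_fun <- function(theta = NULL, log_q = NULL) {
      Qc <- if (is.null(theta)) Q else theta_to_q(theta)
      unlist(lapply(horizons, function(h) project_prevalence(init, Qc, h)))
    }
    prev_grid <- expand.grid(state = 1:3, horizon = horizons)[, 2:1]
    prev <- cbind(prev_grid, with_ci(prev_fun))
    prev$state <- STATE_NAMES[prev$state]
  }

  structure(list(probabilities = probs, length_of_stay = los,
                 sojourn = soj, prevalence = prev,
                 horizons = horizons, qmatrix = Q,
                 has_ci = !is.null(fit), ci_method = if (!is.null(fit)) ci_method),
            class = "transition_summary")
}

#' @export
print.transition_summary <- function(x, digits = 3, ...) {
  cat("Transition summary at horizon(s):",
      paste(x$horizons, collapse = ", "), "year(s)\n")
  cat("\nMean sojourn time (years):\n")
  print(format(x$sojourn, digits = digits), row.names = FALSE)
  cat("\nTransition probabilities:\n")
  p <- x$probabilities
  num <- vapply(p, is.numeric, TRUE) & names(p) != "horizon"
  p[num] <- lapply(p[num], function(v) round(100 * v, 1))
  cat("  (percent)\n")
  print(p, row.names = FALSE)
  cat("\nTotal length of stay (years):\n")
  print(format(x$length_of_stay, digits = digits), row.names = FALSE)
  if (!is.null(x$prevalence)) {
    cat("\nProjected prevalence (percent):\n")
    pr <- x$prevalence
    num <- vapply(pr, is.numeric, TRUE) & names(pr) != "horizon"
    pr[num] <- lapply(pr[num], function(v) round(100 * v, 1))
    print(pr, row.names = FALSE)
  }
  invisible(x)
}

#' Write a transition summary report to disk
#'
#' Emits `probabilities.csv`, `length_of_stay.csv`, `sojourn.csv` and, when
#' present, `prevalence.csv`, plus `validation.json` if a validation table
#' (from [validate_projection()]) is supplied.
#'
#' @param x A [transition_summary()].
#' @param dir Output directory (created if needed).
#' @param validation Optional data.frame from [validate_projection()].
#' @return Invisibly, the paths written.
#' @export
write_transition_report <- function(x, dir, validation = NULL) {
  stopifnot(inherits(x, "transition_summary"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- character(0)
  wr <- function(df, name) {
    p <- file.path(dir, name)
    utils::write.csv(df, p, row.names = FALSE)
    paths <<- c(paths, p)
  }
  wr(x$probabilities, "probabilities.csv")
  wr(x$length_of_stay, "length_of_stay.csv")
  wr(x$sojourn, "sojourn.csv")
  if (!is.null(x$prevalence)) wr(x$prevalence, "prevalence.csv")
  if (!is.null(validation)) {
    p <- file.path(dir, "validation.json")
    jsonlite::write_json(validation, p, auto_unbox = TRUE, digits = NA)
    paths <- c(paths, p)
  }
  invisible(paths)
}
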