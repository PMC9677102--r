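# Three-state continuous-time Markov engine for interval-censored panel data.
# States: 1 = normal weight, 2 = overweight, 3 = obese. Instantaneous jumps
# are restricted to adjacent states (1<->2, 2<->3): a change between normal
# weight and obesity must pass through overweight, though panel observation
# can of course record a 1 -> 3 pair across an examination interval.

STATE_NAMES <- c("normal", "overweight", "obese")

# allowed instantaneous transitions, in parameter order
TRANS <- cbind(from = c(1L, 2L, 2L, 3L), to = c(2L, 1L, 3L, 2L))
TRANS_LABELS <- c("1->2", "2->1", "2->3", "3->2")

#' Build a tridiagonal 3x3 transition intensity matrix
#'
#' Assembles the generator Q of the three-state chain from the four allowed
#' instantaneous rates (per year). Diagonal entries are the negative row
#' sums, and the forbidden normal<->obese cells are identically zero.
#'
#' @param q12,q21,q23,q32 Non-negative intensities (1/year): normal->overweight,
#'   overweight->normal, overweight->obese, obese->overweight.
#' @return 3x3 matrix with state dimnames.
#' @examples
#' intensity_matrix(0.086, 0.341, 0.257, 0.209)
#' @export
intensity_matrix <- function(q12, q21, q23, q32) {
  q <- c(q12, q21, q23, q32)
  if (any(!is.finite(q) | q < 0))
    stop("intensities must be finite and non-negative")
  Q <- matrix(0, 3, 3, dimnames = list(STATE_NAMES, STATE_NAMES))
  Q[TRANS] <- q
  diag(Q) <- -rowSums(Q)
  Q
}

#' Reference transition intensity matrices
#'
#' Published point estimates of the weight-status transition intensities
#' (1/year) for a large cohort of school-age children followed over five
#' annual examinations, overall and by sex. These serve as the simulator's
#' default truth and as desk-scale inputs for the derived summaries; the
#' same values ship as `inst/extdata/reference_intensities.csv`.
#'
#' @param stratum `"all"`, `"girls"` or `"boys"`.
#' @return 3x3 intensity matrix (see [intensity_matrix()]).
#' @export
reference_intensities <- function(stratum = c("all", "girls", "boys")) {
  stratum <- match.arg(stratum)
  switch(stratum,
    all   = intensity_matrix(0.086, 0.341, 0.257, 0.209),
    girls = intensity_matrix(0.066, 0.379, 0.295, 0.290),
    boys  = intensity_matrix(0.111, 0.317, 0.235, 0.172))
}

#' Internal: validate an intensity matrix
#' @noRd
check_q <- function(Q) {
  stopifnot(is.matrix(Q), all(dim(Q) == 3L))
  if (any(!is.finite(Q))) stop("Q has non-finite entries")
  off <- Q; diag(off) <- 0
  if (any(off < -1e-12)) stop("off-diagonal intensities must be non-negative")
  if (any(abs(rowSums(Q)) > 1e-8)) stop("rows of Q must sum to zero")
  if (abs(Q[1, 3]) > 1e-12 || abs(Q[3, 1]) > 1e-12)
    stop("direct normal<->obese intensities must be zero (adjacent-state model)")
  invisible(Q)
}

#' Intensity matrix under a covariate value
#'
#' Proportional-intensities covariate model: each allowed intensity is
#' `q_rs * exp(beta_rs' z)`, i.e. covariates act multiplicatively on each
#' transition rate and `exp(beta)` is the per-unit hazard ratio for that
#' transition. With `beta = NULL` or `z` empty the baseline Q is returned.
#'
#' @param Q Baseline 3x3 intensity matrix.
#' @param beta Numeric matrix (4 rows, one per transition `1->2, 2->1,
#'   2->3, 3->2`; one column per covariate), or a length-4 vector for a
#'   single covariate, or `NULL`.
#' @param z Covariate value(s), matching `ncol(beta)`.
#' @return 3x3 intensity matrix.
#' @export
build_q <- function(Q, beta = NULL, z = NULL) {
  check_q(Q)
  if (is.null(beta) || is.null(z) || length(z) == 0L) return(Q)
  if (is.vector(beta)) beta <- matrix(beta, ncol = 1L)
  stopifnot(nrow(beta) == 4L, ncol(beta) == length(z))
  rates <- Q[TRANS] * exp(as.vector(beta %*% z))
  if (any(!is.finite(rates)))
    stop("non-finite intensity after covariate adjustment")
  intensity_matrix(rates[1L], rates[2L], rates[3L], rates[4L])
}

#' Internal: matrix exponential of a small generator
#'
#' Eigendecomposition path (tridiagonal generators with positive rates are
#' similar to symmetric matrices, so the spectrum is real and eigen is fast
#' and accurate); falls back to Pade scaling-and-squaring ([Matrix::expm()])
#' when the spectrum is complex or the eigenvector basis is ill-conditioned.
#' @noRd
expm3 <- function(M) {
  ev <- eigen(M)
  if (is.complex(ev$values) || anyNA(ev$values)) {
    return(as.matrix(Matrix::expm(M)))
  }
  V <- ev$vectors
  Vi <- tryCatch(solve(V), error = function(e) NULL)
  if (is.null(Vi) || max(abs(V)) * max(abs(Vi)) > 1e8) {
    return(as.matrix(Matrix::expm(M)))
  }
  V %*% (exp(ev$values) * Vi)
}

#' Transition probability matrix P(t) = expm(tQ)
#'
#' For a time-homogeneous chain the interval transition probabilities are
#' the matrix exponential of t times the generator, computed by
#' eigendecomposition of the generator (with a Pade scaling-and-squaring
#' fallback for degenerate spectra). Rows sum to one.
#'
#' @param Q 3x3 intensity matrix.
#' @param t Non-negative horizon in years.
#' @return 3x3 stochastic matrix.
#' @export
transition_probability <- function(Q, t) {
  check_q(Q)
  if (!is.finite(t) || t < 0) stop("'t' must be a non-negative number of years")
  if (t == 0) return(diag(3) + 0 * Q)  # identity with Q's dimnames
  P <- expm3(Q * t)
  dimnames(P) <- dimnames(Q)
  # clip tiny negative round-off
  P[P < 0 & P > -1e-12] <- 0
  P
}

#' Internal: collapse intervals into (dt, z) groups with pair-count matrices
#'
#' The panel likelihood depends on the data only through, per unique
#' (interval length, covariate value), the 3x3 matrix of observed
#' from/to pair counts; grouping once lets every likelihood evaluation
#' reuse the counts and compute one matrix exponential per group.
#' @noRd
group_intervals <- function(iv) {
  has_z <- !is.null(iv$z)
  key <- if (has_z) paste(iv$dt, iv$z) else as.character(iv$dt)
  lapply(split(seq_len(nrow(iv)), key), function(sel) {
    cnt <- matrix(tabulate(iv$from[sel] + 3L * (iv$to[sel] - 1L), 9L), 3L, 3L)
    list(dt = iv$dt[sel[1L]],
         z = if (has_z) iv$z[sel[1L]] else NULL,
         cnt = cnt, pos = which(cnt > 0))
  })
}

#' Internal: log-likelihood of grouped panel intervals
#'
#' The interval-censored panel likelihood is the product over consecutive
#' observation pairs of P_{from,to}(dt; z): the matrix exponential
#' marginalizes the unobserved path between examinations.
#' @noRd
grouped_loglik <- function(groups, Q, beta = NULL) {
  ll <- 0
  for (g in groups) {
    Qk <- if (!is.null(g$z) && !is.null(beta)) build_q(Q, beta, g$z) else Q
    P <- expm3(Qk * g$dt)
    p <- P[g$pos]
    if (any(p <= 0)) return(-Inf)
    ll <- ll + sum(g$cnt[g$pos] * log(p))
  }
  ll
}

#' Panel log-likelihood of an intensity model
#'
#' @param ds A [weight_panel()] (or any data.frame with `child_id`, `t`,
#'   `state` and, if used, the covariate column).
#' @param Q Baseline 3x3 intensity matrix.
#' @param beta Optional length-4 covariate coefficient vector (log-hazard
#'   scale, one per allowed transition).
#' @param covariate Optional covariate column name; its value at the start
#'   of each interval enters the proportional-intensities model
#'   (piecewise-constant convention).
#' @return Log-likelihood (scalar; `-Inf` when an observed pair has zero
#'   probability under `Q`).
#' @export
panel_loglik <- function(ds, Q, beta = NULL, covariate = NULL) {
  check_q(Q)
  iv <- panel_intervals(ds, covariate = covariate)
  grouped_loglik(group_intervals(iv), Q, beta = beta)
}

#' Internal: crude initial intensities from observed pairs
#'
#' Events over person-time: count of r->s pairs (adjacent transitions only)
#' divided by total time spent with the panel observed in state r. Zero
#' counts get a small floor so the optimizer starts in the interior.
#' @noRd
crude_inits <- function(iv) {
  ptime <- vapply(1:3, function(r) sum(iv$dt[iv$from == r]), numeric(1))
  rate <- numeric(4L)
  for (j in seq_len(4L)) {
    n_rs <- sum(iv$from == TRANS[j, 1L] & iv$to == TRANS[j, 2L])
    pt <- max(ptime[TRANS[j, 1L]], 1e-8)
    rate[j] <- max(n_rs, 0.5) / pt
  }
  pmin(pmax(rate, 1e-4), 5)
}

#' Fit the three-state Markov model to panel data by maximum likelihood
#'
#' Maximizes the interval-censored panel likelihood over the four log
#' intensities (log scale guarantees positivity; the two forbidden cells
#' are excluded from the parameter vector entirely) and, when `covariate`
#' is given, over four per-transition covariate coefficients. Optimization
#' is quasi-Newton (L-BFGS-B) from deterministic crude-rate starting values;
#' standard errors come from the numerically differentiated observed
#' information at the optimum.
#'
#' @param ds A [weight_panel()] or data.frame with `child_id`, `t`, `state`
#'   (+ covariate column if used).
#' @param covariate Optional single covariate column name (one covariate at
#'   a time is the first-class design; collinearity among cohort covariates
#'   argues against multi-covariate fits, though `panel_loglik()` accepts a
#'   matrix of coefficients for exploration).
#' @param inits Optional starting intensities (length 4, natural scale);
#'   default crude rates from observed pairs over person-time.
#' @param control Passed to [stats::optim()] (method `L-BFGS-B`).
#' @return Object of class `markov3_fit`: `qmatrix` (MLE with 95% CI),
#'   `theta` (log intensities, then betas), `vcov`, `loglik`, `AIC`,
#'   `n_params`, `covariate`, `beta` (with CI, if fitted), convergence
#'   diagnostics.
#' @export
fit_markov3 <- function(ds, covariate = NULL, inits = NULL, control = list()) {
  iv <- panel_intervals(ds, covariate = covariate)
  if (!nrow(iv)) stop("no observation intervals in panel")
  n_b <- if (is.null(covariate)) 0L else 4L
  if (is.null(inits)) inits <- crude_inits(iv)
  stopifnot(length(inits) == 4L, all(inits > 0))
  groups <- group_intervals(iv)

  # an intensity whose source state never starts an interval leaves the
  # likelihood flat: pin it at (effectively) zero rather than optimize it
  ptime <- vapply(1:3, function(r) sum(iv$dt[iv$from == r]), numeric(1))
  free_q <- which(ptime[TRANS[, 1L]] > 0)
  pinned <- setdiff(seq_len(4L), free_q)
  logq_full <- rep(log(1e-8), 4L)

  expand_theta <- function(par) {
    lq <- logq_full
    lq[free_q] <- par[seq_along(free_q)]
    beta <- if (n_b) par[length(free_q) + seq_len(n_b)] else NULL
    list(logq = lq, beta = beta)
  }
  negll <- function(par) {
    th <- expand_theta(par)
    q <- exp(th$logq)
    Q <- intensity_matrix(q[1L], q[2L], q[3L], q[4L])
    ll <- grouped_loglik(groups, Q, beta = th$beta)
    if (!is.finite(ll)) return(1e10)
    -ll
  }

  par0 <- c(log(inits)[free_q], rep(0, n_b))
  lower <- c(rep(log(1e-8), length(free_q)), rep(-10, n_b))
  upper <- c(rep(log(20), length(free_q)), rep(10, n_b))
  ctrl <- utils::modifyList(list(maxit = 500L, factr = 1e7), control)
  opt <- stats::optim(par0, negll, method = "L-BFGS-B",
                      lower = lower, upper = upper, control = ctrl)
  if (opt$convergence != 0)
    stop("optimizer did not converge (code ", opt$convergence, "): ",
         opt$message, "; last value ", format(-opt$value))
  par <- opt$par
  th <- expand_theta(par)

  H <- pracma::hessian(negll, par)
  V <- tryCatch({
    Vi <- solve(H)
    (Vi + t(Vi)) / 2
  }, error = function(e) matrix(NA_real_, length(par), length(par)))

  # covariance on the full (log q, beta) layout, NA rows for pinned cells
  V_full <- matrix(NA_real_, 4L + n_b, 4L + n_b)
  idx_full <- c(free_q, if (n_b) 4L + seq_len(n_b))
  V_full[idx_full, idx_full] <- V

  q_hat <- exp(th$logq)
  se_logq <- sqrt(pmax(diag(V_full)[1:4], 0))
  Q <- intensity_matrix(q_hat[1L], q_hat[2L], q_hat[3L], q_hat[4L])
  q_tab <- data.frame(
    transition = TRANS_LABELS,
    estimate = q_hat,
    lower = exp(th$logq - 1.96 * se_logq),
    upper = exp(th$logq + 1.96 * se_logq))
  q_tab[pinned, c("lower", "upper")] <- NA_real_

  boundary <- TRANS_LABELS[q_hat < 1e-6]
  if (length(boundary))
    warning("intensity at boundary (no supporting events): ",
            paste(boundary, collapse = ", "))

  beta_tab <- NULL
  if (n_b) {
    b <- th$beta
    se_b <- sqrt(pmax(diag(V_full)[4L + seq_len(n_b)], 0))
    beta_tab <- data.frame(transition = TRANS_LABELS, beta = b, se = se_b)
  }

  structure(list(
    qmatrix = Q, q_table = q_tab,
    theta = c(th$logq, th$beta), vcov = V_full,
    free = idx_full, loglik = -opt$value, n_params = length(par),
    AIC = 2 * opt$value + 2 * length(par),
    covariate = covariate, beta = beta_tab,
    n_intervals = nrow(iv), boundary = boundary, pinned = TRANS_LABELS[pinned],
    convergence = opt$convergence, counts = opt$counts),
    class = "markov3_fit")
}

#' @export
print.markov3_fit <- function(x, ...) {
  cat("Three-state Markov model fit (interval-censored panel likelihood)\n")
  cat(sprintf("  intervals: %d   log-likelihood: %.3f   AIC: %.2f   params: %d\n",
              x$n_intervals, x$loglik, x$AIC, x$n_params))
  cat("  baseline intensities (1/year) with 95% CI:\n")
  print(cbind(transition = x$q_table$transition,
              round(x$q_table[, -1L], 4)), row.names = FALSE)
  if (!is.null(x$beta)) {
    cat(sprintf("  covariate '%s' log-hazard coefficients:\n", x$covariate))
    print(cbind(transition = x$beta$transition, round(x$beta[, -1L], 4)),
          row.names = FALSE)
  }
  if (length(x$boundary))
    cat("  boundary transitions:", paste(x$boundary, collapse = ", "), "\n")
  invisible(x)
}

#' Per-transition hazard ratios with 95% confidence intervals
#'
#' For a covariate fit, the hazard ratio per unit of the covariate on each
#' allowed transition is `exp(beta)`, with Wald interval
#' `exp(beta +/- 1.96 se)`.
#'
#' @param m A `markov3_fit` with a covariate.
#' @return data.frame with `transition`, `hr`, `lower`, `upper`.
#' @export
hazard_ratios <- function(m) {
  stopifnot(inherits(m, "markov3_fit"))
  if (is.null(m$beta))
    stop("model has no covariate; fit with fit_markov3(ds, covariate = ...)")
  data.frame(transition = m$beta$transition,
             hr = exp(m$beta$beta),
             lower = exp(m$beta$beta - 1.96 * m$beta$se),
             upper = exp(m$beta$beta + 1.96 * m$beta$se))
}

#' Likelihood-ratio comparison of nested model fits
#'
#' @param m0 Null (smaller) `markov3_fit`, nested in `m1`.
#' @param m1 Extended `markov3_fit`.
#' @return data.frame with the LRT statistic `2*(l1 - l0)`, degrees of
#'   freedom, chi-squared p-value and `delta_aic = AIC1 - AIC0` (negative
#'   favours the extended model).
#' @export
compare_models <- function(m0, m1) {
  stopifnot(inherits(m0, "markov3_fit"), inherits(m1, "markov3_fit"))
  df <- m1$n_params - m0$n_params
  if (df < 0) stop("'m1' must be the larger model")
  lrt <- 2 * (m1$loglik - m0$loglik)
  if (lrt < -1e-6)
    stop("extended model has lower likelihood than the null (",
         format(lrt), "); models not nested or fit not converged")
  lrt <- max(lrt, 0)
  p <- if (df == 0) 1 else stats::pchisq(lrt, df, lower.tail = FALSE)
  data.frame(lrt = lrt, df = df, p_value = p, delta_aic = m1$AIC - m0$AIC)
}

#' Serialize a fit to JSON
#'
#' @param m A `markov3_fit`.
#' @param path Optional output path; if `NULL`, the JSON string is returned.
#' @return Invisibly, the JSON string.
#' @export
fit_to_json <- function(m, path = NULL) {
  stopifnot(inherits(m, "markov3_fit"))
  obj <- list(q_table = m$q_table, beta = m$beta, loglik = m$loglik,
              AIC = m$AIC, n_params = m$n_params, covariate = m$covariate,
              vcov = m$vcov, boundary = m$boundary,
              convergence = m$convergence)
  js <- jsonlite::toJSON(obj, auto_unbox = TRUE, digits = NA, null = "null")
  if (!is.null(path)) writeLines(js, path)
  invisible(js)
}
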