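# Independent numerical oracles and tiny fixtures shared across tests.

# Truncated-Taylor matrix exponential with scaling and squaring; kept
# deliberately naive and independent of the package's eigendecomposition /
# Pade paths so the two can cross-check each other.
taylor_expm <- function(M, order = 40L) {
  s <- max(0L, ceiling(log2(max(1, norm(M, "1")))))
  A <- M / 2^s
  P <- term <- diag(nrow(M))
  for (k in seq_len(order)) {
    term <- term %*% A / k
    P <- P + term
  }
  for (i in seq_len(s)) P <- P %*% P
  P
}

# random valid tridiagonal generator
random_q <- function(max_rate = 1) {
  r <- stats::runif(4, 0.01, max_rate)
  intensity_matrix(r[1], r[2], r[3], r[4])
}

# minimal three-wave single-child panel data.frame
tiny_panel_df <- function(ages = c(6.8, 7.8, 8.8),
                          heights = c(122.4, 128.1, 133.5),
                          weights = c(23.8, 26.4, 29.3),
                          id = "k1", sex = "girl", area = "urban") {
  data.frame(child_id = id, sex = sex, area = area,
             exam_age = ages, height = heights, weight = weights)
}

# fixture cutoff table used by the classification examples:
# one bracket per sex covering ages 5-12 with thresholds 17 / 19
flat_cutoffs <- function() {
  cutoff_table(data.frame(sex = rep(c("girl", "boy"), each = 1),
                          age_lo = 5, age_hi = 12,
                          c_ow = 17, c_ob = 19),
               provenance = "test-fixture")
}

# states-only panel simulated from Q: helper around the internal generator
sim_states_panel <- function(Q, n, waves = 6L, spacing = 1) {
  start <- sample.int(3L, n, replace = TRUE, prob = c(0.711, 0.181, 0.108))
  times <- (seq_len(waves) - 1L) * spacing
  wstrans:::simulate_panel_states(rep(list(Q), n), start,
                                  rep(list(times), n))
}
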