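# Shared fixtures: a default environment and a fast fitting control for
# unit tests (fewer restarts; the deterministic OLS-based starts dominate).

test_env <- function() task_environment()

fast_control <- function(seed = 1L) fit_control(n_restarts = 3L, seed = seed)

# independent brute-force similarity prediction: plain loops, no shared code
oracle_similarity <- function(x1, x2, exemplars, w, h) {
  num <- 0; den <- 0
  for (j in seq_len(nrow(exemplars))) {
    d <- w[1] * abs(x1 - exemplars$x1[j]) + w[2] * abs(x2 - exemplars$x2[j])
    s <- exp(-h * d)
    num <- num + s * exemplars$criterion[j]
    den <- den + s
  }
  num / den
}

# independent Kendall tau-b by O(n^2) pair counting with tie correction
oracle_kendall <- function(x, y) {
  n <- length(x)
  conc <- disc <- tx <- ty <- 0
  for (i in 1:(n - 1)) for (j in (i + 1):n) {
    dx <- sign(x[i] - x[j]); dy <- sign(y[i] - y[j])
    if (dx == 0 && dy == 0) next
    if (dx == 0) tx <- tx + 1
    else if (dy == 0) ty <- ty + 1
    else if (dx == dy) conc <- conc + 1
    else disc <- disc + 1
  }
  n0 <- n * (n - 1) / 2
  (conc - disc) / sqrt((n0 - count_tie_pairs(x)) * (n0 - count_tie_pairs(y)))
}

count_tie_pairs <- function(v) {
  sum(vapply(table(v), function(t) t * (t - 1) / 2, numeric(1)))
}
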