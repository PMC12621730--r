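# Shared fixtures, built in code.

# Tiny uncensored dataset with distinct times.
tiny_surv <- function(n = 6, seed = 1) {
  set.seed(seed)
  list(x = matrix(rnorm(n * 2), n, 2, dimnames = list(NULL, c("a", "b"))),
       time = seq_len(n) + 0.5,
       status = rep(1L, n))
}

# Linear proportional-hazards data with known coefficients, exponential
# baseline, independent exponential censoring.
linear_ph_data <- function(n, beta, cens_rate = 0.3, seed = 1) {
  set.seed(seed)
  p <- length(beta)
  x <- matrix(rnorm(n * p), n, p, dimnames = list(NULL, paste0("V", seq_len(p))))
  t_true <- rexp(n, rate = exp(as.vector(x %*% beta)))
  cens <- rexp(n, rate = cens_rate)
  list(x = x, time = pmin(t_true, cens), status = as.integer(t_true <= cens))
}

# O(n^2) reference implementation of the strict-inequality concordance index.
cindex_bruteforce <- function(risk, time, status, half_ties = FALSE) {
  num <- 0
  den <- 0
  n <- length(risk)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i == j) next
    if (time[i] > time[j] && status[j] == 1) {
      den <- den + 1
      if (risk[i] < risk[j]) num <- num + 1
      else if (half_ties && risk[i] == risk[j]) num <- num + 0.5
    }
  }
  num / den
}

# Double-loop reference for the negative mean partial log-likelihood.
negpll_bruteforce <- function(risk, time, status) {
  total <- 0
  for (i in which(status == 1)) {
    total <- total + risk[i] - log(sum(exp(risk[time >= time[i]])))
  }
  -total / sum(status == 1)
}
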