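#' Simulate right-censored survival data with linear or non-linear risk
#'
#' Generates training and test sets from a proportional-hazards model with a
#' Gompertz baseline hazard \eqn{\lambda e^{\gamma t}} and independent Weibull
#' censoring. Features comprise four blocks of `p0` correlated standard-normal
#' covariates (`X1..X{4 p0}`, compound-symmetry correlation `rho` within each
#' block, blocks mutually independent) and `p0` independent Bernoulli
#' covariates (`Z1..Z{p0}`).
#'
#' Two risk functions are available. Scenario 1 is linear:
#' \deqn{\xi(x) = \alpha (0.2 x_1 + 0.4 x_{p_0+1} + 0.6 x_{2p_0+1} +
#'   0.8 x_{3p_0+1} + z_1).}
#' Scenario 2 adds a quadratic and interaction terms:
#' \deqn{\xi(x) = \alpha (z_1 + 2 x_1 z_2 + 0.5 x_{p_0+1}^2 +
#'   x_{2p_0+1} x_{3p_0+1}).}
#'
#' Event times are drawn by inverting the Gompertz-PH cumulative hazard in
#' closed form; observed time is the minimum of event and censoring time and
#' `status` indicates an observed event. The test set is an independent fresh
#' draw from the same law.
#'
#' @param scenario 1 (linear) or 2 (non-linear).
#' @param n training-set size.
#' @param test_n test-set size (default `n / 5`, the 80/20 convention).
#' @param p0 block size; total feature count is `5 * p0`.
#' @param rho within-block correlation, in `[0, 1)`.
#' @param alpha effect scale; defaults to `1000 / n` so effects shrink as the
#'   sample grows.
#' @param gompertz_gamma,gompertz_lambda baseline hazard parameters
#'   \eqn{\gamma}, \eqn{\lambda}.
#' @param weibull_shape,weibull_scale censoring-time Weibull parameters, with
#'   survival \eqn{S(t) = \exp(-(t/\mathrm{scale})^{\mathrm{shape}})}.
#' @param bernoulli_p success probability of the binary covariates.
#' @param seed integer seed; the draw is reproducible given the seed.
#' @return An object of class `"survsim"`: a list with data frames `train` and
#'   `test` (columns `X1..`, `Z1..`, `time`, `status`) and the generating
#'   parameters.
#' @examples
#' sim <- simulate_survdata(scenario = 1, n = 200, seed = 1)
#' head(sim$train[, c("X1", "Z1", "time", "status")])
#' @export
simulate_survdata <- function(scenario = 1, n = 1000, test_n = round(n / 5),
                              p0 = 10, rho = 0, alpha = 1000 / n,
                              gompertz_gamma = 3, gompertz_lambda = 2e-5,
                              weibull_shape = 1.5, weibull_scale = 3.5,
                              bernoulli_p = 0.4, seed = NULL) {
  stopifnot(scenario %in% c(1, 2), n >= 1, test_n >= 0, p0 >= 1, alpha > 0,
            gompertz_gamma > 0, gompertz_lambda > 0,
            weibull_shape > 0, weibull_scale > 0,
            bernoulli_p > 0, bernoulli_p < 1)
  if (rho < 0 || rho >= 1)
    stop("rho must lie in [0, 1)")
  if (!is.null(seed)) set.seed(seed)

  draw <- function(m) {
    if (m == 0) return(NULL)
    X <- make_features(m, p0 = p0, rho = rho, bernoulli_p = bernoulli_p)
    xi <- linear_predictor(scenario, X, alpha = alpha)
    t_true <- sample_event_time(xi, gamma = gompertz_gamma,
                                lambda = gompertz_lambda)
    cens <- stats::rweibull(m, shape = weibull_shape, scale = weibull_scale)
    out <- as.data.frame(X)
    out$time <- pmin(t_true, cens)
    out$status <- as.integer(t_true <= cens)
    out
  }

  structure(list(train = draw(n), test = draw(test_n), scenario = scenario,
                 n = n, test_n = test_n, p0 = p0, rho = rho, alpha = alpha,
                 gompertz_gamma = gompertz_gamma,
                 gompertz_lambda = gompertz_lambda,
                 weibull_shape = weibull_shape, weibull_scale = weibull_scale,
                 bernoulli_p = bernoulli_p, seed = seed),
            class = "survsim")
}

#' @export
print.survsim <- function(x, ...) {
  cat(sprintf("Simulated survival data (scenario %d)\n", x$scenario))
  cat(sprintf("  train n = %d, test n = %d, p = %d, rho = %g, alpha = %g\n",
              x$n, x$test_n, 5L * x$p0, x$rho, x$alpha))
  cat(sprintf("  train events: %d (%.1f%%)\n", sum(x$train$status),
              100 * mean(x$train$status)))
  invisible(x)
}

#' Draw the feature matrix
#'
#' Columns `1..4*p0` are multivariate normal with block-diagonal covariance:
#' four `p0 x p0` compound-symmetry blocks (unit diagonal, off-diagonal `rho`).
#' Columns `4*p0 + 1 .. 5*p0` are independent Bernoulli(`bernoulli_p`).
#' Column names are `X1..X{4 p0}`, `Z1..Z{p0}`. Uses the current RNG state.
#'
#' @param n number of rows.
#' @inheritParams simulate_survdata
#' @return an `n x 5*p0` numeric matrix.
#' @export
make_features <- function(n, p0 = 10, rho = 0, bernoulli_p = 0.4) {
  if (rho < 0 || rho >= 1)
    stop("rho must lie in [0, 1)")
  # CS(rho) = rho * J + (1 - rho) * I: shared factor + independent noise
  cont <- matrix(0, n, 4 * p0)
  for (blk in 0:3) {
    shared <- stats::rnorm(n)
    noise <- matrix(stats::rnorm(n * p0), n, p0)
    cont[, blk * p0 + seq_len(p0)] <-
      sqrt(rho) * shared + sqrt(1 - rho) * noise
  }
  bin <- matrix(stats::rbinom(n * p0, 1, bernoulli_p), n, p0)
  X <- cbind(cont, bin)
  colnames(X) <- c(paste0("X", seq_len(4 * p0)), paste0("Z", seq_len(p0)))
  X
}

#' Evaluate the true log relative-risk function
#'
#' @param scenario 1 or 2; see [simulate_survdata()].
#' @param X feature matrix with `5 * p0` columns in the generator's order.
#' @param alpha effect scale.
#' @return length-`nrow(X)` numeric vector \eqn{\xi(x)}.
#' @export
linear_predictor <- function(scenario, X, alpha = 1) {
  X <- as.matrix(X)
  if (ncol(X) %% 5 != 0)
    stop("X must have 5 * p0 columns")
  p0 <- ncol(X) / 5
  x1 <- X[, 1]; x2 <- X[, p0 + 1]; x3 <- X[, 2 * p0 + 1]; x4 <- X[, 3 * p0 + 1]
  z1 <- X[, 4 * p0 + 1]
  if (scenario == 1) {
    alpha * (0.2 * x1 + 0.4 * x2 + 0.6 * x3 + 0.8 * x4 + z1)
  } else if (scenario == 2) {
    z2 <- X[, 4 * p0 + 2]
    alpha * (z1 + 2 * x1 * z2 + 0.5 * x2^2 + x3 * x4)
  } else {
    stop("scenario must be 1 or 2")
  }
}

#' Sample event times from the Gompertz proportional-hazards model
#'
#' Hazard \eqn{h(t \mid x) = \lambda e^{\gamma t} e^{\xi}}. With
#' \eqn{E \sim \mathrm{Exp}(1)}, the inverse of the cumulative hazard gives
#' \eqn{T = \gamma^{-1} \log(1 + \gamma E / (\lambda e^{\xi}))}.
#'
#' @param xi log relative risks (vector); one time is drawn per element.
#' @param gamma,lambda Gompertz parameters, both positive.
#' @param e optional Exp(1) draws (for deterministic checks); defaults to
#'   fresh draws from the current RNG.
#' @return positive event times, same length as `xi`.
#' @export
sample_event_time <- function(xi, gamma = 3, lambda = 2e-5, e = NULL) {
  stopifnot(gamma > 0, lambda > 0)
  if (is.null(e)) e <- stats::rexp(length(xi))
  log1p(gamma * e / (lambda * exp(xi))) / gamma
}

#' Read and write delimited survival data
#'
#' Comma-separated files with a header row: one column per feature plus `time`
#' and `status`. `read_surv_csv` validates that times are positive and status
#' is 0/1.
#'
#' @param data data frame with `time` and `status` columns.
#' @param path file path.
#' @return `read_surv_csv` returns the validated data frame.
#' @export
write_surv_csv <- function(data, path) {
  stopifnot(all(c("time", "status") %in% names(data)))
  utils::write.csv(data, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_surv_csv
#' @export
read_surv_csv <- function(path) {
  data <- utils::read.csv(path)
  if (!all(c("time", "status") %in% names(data)))
    stop("file must contain 'time' and 'status' columns")
  if (any(!is.finite(data$time)) || any(data$time <= 0))
    stop("all times must be positive and finite")
  if (!all(data$status %in% c(0, 1)))
    stop("status must be 0/1")
  if (anyNA(data)) stop("missing values are not supported")
  data
}

# Split a survival data frame into (X, time, status); internal.
surv_parts <- function(data) {
  stopifnot(is.data.frame(data), all(c("time", "status") %in% names(data)))
  feat <- setdiff(names(data), c("time", "status"))
  list(x = as.matrix(data[, feat, drop = FALSE]),
       time = as.numeric(data$time),
       status = as.integer(data$status))
}
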