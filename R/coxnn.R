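#' Fit a single Cox partial-likelihood neural network
#'
#' A feed-forward network with ReLU hidden layers and a scalar affine output
#' models the log relative risk \eqn{\xi(x)} of a proportional-hazards model.
#' Training minimizes the negative mean Cox partial log-likelihood (Breslow
#' risk sets, formed within each mini-batch) plus an L1 penalty on the weight
#' matrices, by mini-batch Adam. Because the partial likelihood identifies
#' \eqn{\xi} only up to an additive constant, the output is centered after
#' training so that the mean fitted risk over the training rows is zero
#' (equivalent to constraining the output-layer bias).
#'
#' @param x feature matrix (or, for the formula method, a model formula with a
#'   [survival::Surv()] response).
#' @param time,status observed times (positive) and 0/1 event indicators.
#' @param hidden integer vector of hidden-layer sizes; at least one layer.
#' @param l1 L1 penalty weight on the network weights (biases excluded).
#' @param learn_rate Adam learning rate.
#' @param batch_size mini-batch size, at least 2 (a partial-likelihood batch
#'   needs a non-trivial risk set). Batches without events are skipped.
#' @param epochs number of passes over the training data.
#' @param seed integer seed controlling initialization and batch shuffling;
#'   the fit is reproducible given the seed.
#' @param ... passed between methods.
#' @return An object of class `"coxnn"` with elements `weights`, `biases`,
#'   `offset` (the centering constant), `config` and `feature_names`.
#'   `predict()` returns centered risk scores.
#' @seealso [survnn()] for the bagged-and-filtered ensemble.
#' @examples
#' sim <- simulate_survdata(scenario = 1, n = 300, seed = 1)
#' fit <- coxnn(Surv(time, status) ~ ., data = sim$train,
#'              hidden = c(16, 8), epochs = 20, seed = 1)
#' risk <- predict(fit, sim$test)
#' @export
coxnn <- function(x, ...) UseMethod("coxnn")

#' @rdname coxnn
#' @param formula a formula whose left side is `Surv(time, status)`.
#' @param data data frame holding the variables in `formula`.
#' @export
coxnn.formula <- function(formula, data, ...) {
  parts <- parse_surv_formula(formula, data)
  fit <- coxnn.default(parts$x, parts$time, parts$status, ...)
  fit$formula <- formula
  fit
}

#' @rdname coxnn
#' @export
coxnn.default <- function(x, time, status, hidden = c(50, 20), l1 = 1e-4,
                          learn_rate = 1e-3, batch_size = 128, epochs = 200,
                          seed = NULL, ...) {
  x <- as.matrix(x)
  status <- as.integer(status)
  check_survdata(x, time, status)
  if (sum(status) < 2) stop("training data must contain at least 2 events")
  stopifnot(length(hidden) >= 1, all(hidden >= 1), batch_size >= 2,
            epochs >= 1, l1 >= 0, learn_rate > 0)
  if (is.null(seed)) seed <- sample.int(.Machine$integer.max, 1)

  trained <- cpp_train_net(x, as.numeric(time), status,
                           as.integer(hidden), l1, learn_rate,
                           as.integer(batch_size), as.integer(epochs),
                           as.integer(seed))
  raw <- cpp_forward(trained$weights, trained$biases, x)
  fit <- structure(list(weights = trained$weights, biases = trained$biases,
                        offset = mean(raw),
                        skipped_batches = trained$skipped_batches,
                        config = list(hidden = as.integer(hidden), l1 = l1,
                                      learn_rate = learn_rate,
                                      batch_size = as.integer(batch_size),
                                      epochs = as.integer(epochs)),
                        seed = as.integer(seed),
                        feature_names = colnames(x)),
                   class = "coxnn")
  fit
}

#' Predict centered log relative risks from a fitted network
#'
#' Row `i` of the output depends only on row `i` of the input; the training-set
#' centering constant is subtracted.
#'
#' @param object a `"coxnn"` fit.
#' @param newdata feature matrix or data frame (extra `time`/`status` columns
#'   are ignored).
#' @param ... unused.
#' @return numeric risk vector.
#' @export
predict.coxnn <- function(object, newdata, ...) {
  x <- extract_features(newdata, object$feature_names)
  as.numeric(cpp_forward(object$weights, object$biases, x)) - object$offset
}

#' @export
print.coxnn <- function(x, ...) {
  cat(sprintf("Cox partial-likelihood network: %s -> %s -> 1\n",
              length(x$feature_names),
              paste(x$config$hidden, collapse = " -> ")))
  cat(sprintf("  l1 = %g, lr = %g, batch = %d, epochs = %d, seed = %d\n",
              x$config$l1, x$config$learn_rate, x$config$batch_size,
              x$config$epochs, x$seed))
  invisible(x)
}

#' @export
refit.coxnn <- function(object, x, time, status, seed = object$seed, ...) {
  coxnn.default(x, time, status, hidden = object$config$hidden,
                l1 = object$config$l1, learn_rate = object$config$learn_rate,
                batch_size = object$config$batch_size,
                epochs = object$config$epochs, seed = seed)
}

#' Negative mean Cox partial log-likelihood
#'
#' \deqn{-\frac{1}{n_{\delta=1}} \sum_{i: \delta_i = 1} \Big(\xi_i -
#'   \log \sum_{j: T_j \ge T_i} e^{\xi_j}\Big)}
#' Risk sets use \eqn{T_j \ge T_i} (Breslow handling of ties); the inner sum is
#' stabilized by max-subtraction. Shifting all risks by a constant leaves the
#' value unchanged.
#'
#' @param risk predicted log relative risks.
#' @param time,status observed times and 0/1 event indicators.
#' @return a single numeric value; errors when no events are present.
#' @export
neg_partial_loglik <- function(risk, time, status) {
  status <- as.integer(status)
  if (sum(status) < 1) stop("partial likelihood undefined: no events")
  cpp_negpll(as.numeric(risk), as.numeric(time), status)
}

#' Refit a model of the same class on new data
#'
#' Generic used by [permfit()] cross-fitting: re-estimates a fitted model's
#' parameters on `(x, time, status)` keeping its hyperparameters.
#'
#' @param object a fitted model.
#' @param x,time,status training data for the refit.
#' @param ... method-specific arguments (e.g. `seed`).
#' @export
refit <- function(object, x, time, status, ...) UseMethod("refit")

# ---- shared input helpers ----

check_survdata <- function(x, time, status) {
  if (nrow(x) != length(time) || nrow(x) != length(status))
    stop("x, time and status must have matching lengths")
  if (anyNA(x) || anyNA(time) || anyNA(status))
    stop("missing values are not supported")
  if (any(time <= 0)) stop("all times must be strictly positive")
  if (!all(status %in% c(0L, 1L))) stop("status must be 0/1")
  invisible(TRUE)
}

parse_surv_formula <- function(formula, data) {
  mf <- stats::model.frame(formula, data)
  y <- stats::model.response(mf)
  if (!inherits(y, "Surv")) stop("response must be a survival::Surv object")
  x <- stats::model.matrix(stats::terms(formula, data = data), mf)
  x <- x[, setdiff(colnames(x), "(Intercept)"), drop = FALSE]
  list(x = x, time = as.numeric(y[, "time"]), status = as.integer(y[, "status"]))
}

extract_features <- function(newdata, feature_names) {
  if (is.data.frame(newdata)) {
    if (!is.null(feature_names) && all(feature_names %in% names(newdata)))
      newdata <- newdata[, feature_names, drop = FALSE]
    else
      newdata <- newdata[, setdiff(names(newdata), c("time", "status")),
                         drop = FALSE]
  }
  as.matrix(newdata)
}

#' @importFrom survival Surv
#' @export
survival::Surv
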