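#' Linear Cox proportional-hazards comparator
#'
#' A thin wrapper around [survival::coxph()] with Breslow tie handling,
#' exposing coefficients, standard errors, two-sided Wald p-values and the
#' Breslow cumulative baseline hazard. Zero-variance feature columns are
#' dropped with a warning (their coefficient is not estimable).
#'
#' @inheritParams coxnn
#' @return An object of class `"coxlin"` with elements `beta`, `se`, `wald_p`,
#'   `baseline` (data frame `time`, `hazard`), `converged` and the underlying
#'   `coxph` fit. `predict()` returns the uncentered linear predictor
#'   \eqn{x'\hat\beta}.
#' @examples
#' sim <- simulate_survdata(scenario = 1, n = 500, seed = 3)
#' fit <- coxlin(Surv(time, status) ~ ., data = sim$train)
#' head(fit$wald_p)
#' @export
coxlin <- function(x, ...) UseMethod("coxlin")

#' @rdname coxlin
#' @export
coxlin.formula <- function(formula, data, ...) {
  parts <- parse_surv_formula(formula, data)
  fit <- coxlin.default(parts$x, parts$time, parts$status, ...)
  fit$formula <- formula
  fit
}

#' @rdname coxlin
#' @export
coxlin.default <- function(x, time, status, ...) {
  x <- as.matrix(x)
  status <- as.integer(status)
  check_survdata(x, time, status)
  if (sum(status) < 2) stop("training data must contain at least 2 events")
  if (is.null(colnames(x))) colnames(x) <- paste0("V", seq_len(ncol(x)))

  const <- apply(x, 2, function(col) length(unique(col)) < 2)
  if (any(const)) {
    warning(sprintf("dropping constant column(s): %s",
                    paste(colnames(x)[const], collapse = ", ")))
    x <- x[, !const, drop = FALSE]
  }

  fit <- survival::coxph(survival::Surv(time, status) ~ x,
                         ties = "breslow",
                         control = survival::coxph.control(iter.max = 50))
  beta <- stats::coef(fit)
  names(beta) <- colnames(x)
  se <- sqrt(diag(fit$var))
  names(se) <- colnames(x)
  z <- beta / se
  conv <- fit$iter < 50 && all(is.finite(beta)) && all(is.finite(se))
  lp <- as.numeric(x %*% beta)

  structure(list(beta = beta, se = se, wald_z = z,
                 wald_p = 2 * stats::pnorm(-abs(z)),
                 baseline = breslow_cumhaz(lp, time, status),
                 converged = conv, iter = fit$iter, coxph = fit,
                 feature_names = colnames(x)),
            class = "coxlin")
}

#' @export
print.coxlin <- function(x, ...) {
  cat(sprintf("Linear Cox model (Breslow ties), %d features%s\n",
              length(x$beta), if (x$converged) "" else " [NOT CONVERGED]"))
  print(data.frame(beta = x$beta, se = x$se, z = x$wald_z, p = x$wald_p))
  invisible(x)
}

#' @rdname predict.coxnn
#' @export
predict.coxlin <- function(object, newdata, ...) {
  x <- extract_features(newdata, object$feature_names)
  if (!identical(colnames(x), object$feature_names))
    x <- x[, object$feature_names, drop = FALSE]
  as.numeric(x %*% object$beta)
}

#' @export
refit.coxlin <- function(object, x, time, status, ...) {
  coxlin.default(x, time, status)
}

#' Breslow cumulative baseline hazard
#'
#' \deqn{\hat H_0(t) = \sum_{t_k \le t} d_k / \sum_{j: T_j \ge t_k} e^{\xi_j}}
#' over distinct event times \eqn{t_k} with event counts \eqn{d_k}. The result
#' is nondecreasing, right-continuous and 0 at `t = 0`.
#'
#' @param risk log relative risks on the training data (on the same scale later
#'   passed to [predict_survival()]).
#' @param time,status training outcomes.
#' @return data frame with columns `time` (distinct event times, increasing)
#'   and `hazard` (cumulative baseline hazard).
#' @export
breslow_cumhaz <- function(risk, time, status) {
  status <- as.integer(status)
  ev_times <- sort(unique(time[status == 1]))
  erisk <- exp(risk)
  haz <- vapply(ev_times, function(tk) {
    sum(status == 1 & time == tk) / sum(erisk[time >= tk])
  }, numeric(1))
  data.frame(time = ev_times, hazard = cumsum(haz))
}

#' Predicted survival probabilities
#'
#' \eqn{\hat S(t \mid x) = \exp(-\hat H_0(t) e^{\hat\xi(x)})} using the fit's
#' Breslow baseline and its risk predictions. Works for both the linear Cox
#' comparator and the bagged network ensemble (whose baseline is computed from
#' the ensemble risks on the training data).
#'
#' @param object a `"coxlin"` or `"survnn"` fit.
#' @param newdata feature rows.
#' @param times evaluation times (non-negative).
#' @return matrix of survival probabilities, `nrow(newdata)` x `length(times)`.
#' @export
predict_survival <- function(object, newdata, times) {
  stopifnot(all(times >= 0), !is.null(object$baseline))
  risk <- predict(object, newdata)
  H0 <- eval_step(stats::stepfun(object$baseline$time, c(0, object$baseline$hazard)),
                  times)
  outer(exp(risk), H0, function(er, h) exp(-h * er))
}

eval_step <- function(f, t) as.numeric(f(t))
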