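#' Harrell's concordance index for risk predictions
#'
#' Counts ordered pairs \eqn{(i, j)} with \eqn{T_i > T_j} and \eqn{\delta_j =
#' 1} (the shorter time is an observed event, so the pair is comparable) and
#' returns the fraction for which \eqn{\hat\xi_i < \hat\xi_j} — the
#' longer-lived subject has the lower predicted risk. With `ties = "none"`
#' (the default) tied predictions contribute 0, a literal strict-inequality
#' reading; `ties = "half"` is the common convention counting them 1/2.
#'
#' @param risk predicted log relative risks.
#' @param time,status observed times and 0/1 event indicators.
#' @param ties `"none"` or `"half"`.
#' @return a value in `[0, 1]`; errors when no pair is comparable.
#' @examples
#' c_index(c(3, 2, 1), time = c(1, 2, 3), status = c(1, 1, 1))  # 1
#' @export
c_index <- function(risk, time, status, ties = c("none", "half")) {
  ties <- match.arg(ties)
  cpp_cindex(as.numeric(risk), as.numeric(time), as.integer(status),
             ties == "half")
}

#' Kaplan-Meier estimate of the censoring survival function
#'
#' The product-limit estimator applied with censoring (`status == 0`) as the
#' event, i.e. an estimate of \eqn{G(t) = P(C > t)}. Used as the
#' inverse-probability-of-censoring weight in [brier_score()].
#'
#' @inheritParams c_index
#' @return An object of class `"step_surv"`: a right-continuous nonincreasing
#'   step function starting at 1, with fields `time` and `surv`. Evaluate it
#'   with [eval_surv()].
#' @export
km_censoring <- function(time, status) {
  km <- survival::survfit(survival::Surv(time, 1 - as.integer(status)) ~ 1)
  structure(list(time = km$time, surv = km$surv), class = "step_surv")
}

#' Evaluate a step survival function
#'
#' @param fit a `"step_surv"` object.
#' @param t evaluation times.
#' @param left if `TRUE`, return the left limit \eqn{G(t^-)} (the probability
#'   of remaining uncensored just before `t`).
#' @return numeric vector of survival probabilities; values before the first
#'   jump are 1.
#' @export
eval_surv <- function(fit, t, left = FALSE) {
  stopifnot(inherits(fit, "step_surv"))
  f <- stats::stepfun(fit$time, c(1, fit$surv), right = left)
  as.numeric(f(t))
}

#' @export
print.step_surv <- function(x, ...) {
  cat(sprintf("Step survival function: %d jump times, final value %.4f\n",
              length(x$time), x$surv[length(x$surv)]))
  invisible(x)
}

#' Inverse-probability-of-censoring-weighted Brier score at a time point
#'
#' \deqn{BS(t) = \frac{1}{n} \sum_i \Big[ \frac{\hat S(t \mid x_i)^2
#'   I(T_i \le t, \delta_i = 1)}{\hat G(T_i^-)} +
#'   \frac{(1 - \hat S(t \mid x_i))^2 I(T_i > t)}{\hat G(t)} \Big]}
#' Subjects censored before `t` contribute 0. Events are weighted by the
#' censoring survival just before the event time (left limit). Terms whose
#' weight denominator is 0 are excluded with a warning.
#'
#' @param t evaluation time.
#' @param surv_prob per-subject predicted survival probabilities at `t`.
#' @param time,status observed outcomes.
#' @param cens_surv censoring survival function from [km_censoring()]; if
#'   omitted it is estimated from `time`, `status`.
#' @return a nonnegative number.
#' @export
brier_score <- function(t, surv_prob, time, status, cens_surv = NULL) {
  status <- as.integer(status)
  n <- length(time)
  stopifnot(length(surv_prob) == n, length(status) == n)
  if (is.null(cens_surv)) cens_surv <- km_censoring(time, status)
  g_event <- eval_surv(cens_surv, time, left = TRUE)
  g_t <- eval_surv(cens_surv, t)

  past_event <- time <= t & status == 1
  at_risk <- time > t
  contrib <- numeric(n)
  bad <- (past_event & g_event == 0) | (at_risk & g_t == 0)
  if (any(bad)) {
    warning(sprintf("%d term(s) excluded: censoring weight is 0", sum(bad)))
    past_event <- past_event & !bad
    at_risk <- at_risk & !bad
  }
  contrib[past_event] <- surv_prob[past_event]^2 / g_event[past_event]
  contrib[at_risk] <- (1 - surv_prob[at_risk])^2 / g_t
  sum(contrib) / n
}

#' Integrated Brier score by the trapezoidal rule
#'
#' \deqn{IBS = \frac{1}{t_2 - t_1} \int_{t_1}^{t_2} BS(s)\, ds}
#' approximated on the supplied grid.
#'
#' @param grid increasing evaluation times spanning `[t1, t2]`.
#' @param bs Brier-score values on `grid`.
#' @param t1,t2 integration limits; default to the grid range.
#' @return the time-averaged Brier score.
#' @export
ibs <- function(grid, bs, t1 = min(grid), t2 = max(grid)) {
  if (length(grid) < 2) stop("need at least 2 grid points")
  stopifnot(length(grid) == length(bs), t1 < t2)
  if (is.unsorted(grid, strictly = TRUE)) stop("grid must be increasing")
  sum(diff(grid) * (utils::head(bs, -1) + utils::tail(bs, -1)) / 2) / (t2 - t1)
}

#' Integrated Brier score of a fitted model on a test set
#'
#' Convenience driver: evaluates [predict_survival()] on the sorted distinct
#' observed test times (the duration of the test set), computes the IPCW Brier
#' score at each with the censoring distribution estimated from the test set,
#' and integrates by the trapezoidal rule.
#'
#' @param object a fit supported by [predict_survival()].
#' @param data test data frame with `time` and `status`.
#' @return the integrated Brier score.
#' @export
integrated_brier <- function(object, data) {
  parts <- surv_parts(data)
  grid <- sort(unique(parts$time))
  if (length(grid) < 2) stop("need at least 2 distinct test times")
  S <- predict_survival(object, parts$x, grid)
  G <- km_censoring(parts$time, parts$status)
  bs <- vapply(seq_along(grid), function(k)
    brier_score(grid[k], S[, k], parts$time, parts$status, G), numeric(1))
  ibs(grid, bs)
}
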