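#' Bagged and filtered Cox neural network
#'
#' Fits `n_bag` networks ([coxnn()]) on bootstrap resamples of the training
#' data, scores each on its out-of-bag (OOB) subjects by the mean OOB log
#' partial likelihood, ranks members best-fit-first, and averages only the top
#' `q_opt` members, where `q_opt` minimizes the training-set negative mean
#' partial log-likelihood of the running ensemble average. With `q_opt` equal
#' to `n_bag` this reduces to classical bagging; the filtering step exists to
#' drop members whose random initialization led them to a poor fit.
#'
#' @inheritParams coxnn
#' @param n_bag number of bootstrap members (B).
#' @param ... passed on to [coxnn()] (architecture and training options).
#' @return An object of class `"survnn"`: `members` (the fitted networks),
#'   `oob_loglik` (per-member OOB mean log partial likelihood, higher is
#'   better), `order` (ranking permutation, best first), `q_opt`, and
#'   `baseline` (Breslow cumulative baseline hazard of the ensemble risks on
#'   the training data, used by [predict_survival()]).
#' @examples
#' sim <- simulate_survdata(scenario = 2, n = 300, seed = 7)
#' fit <- survnn(Surv(time, status) ~ ., data = sim$train, n_bag = 3,
#'               hidden = c(16, 8), epochs = 20, seed = 7)
#' c_index(predict(fit, sim$test), sim$test$time, sim$test$status)
#' @export
survnn <- function(x, ...) UseMethod("survnn")

#' @rdname survnn
#' @export
survnn.formula <- function(formula, data, ...) {
  parts <- parse_surv_formula(formula, data)
  fit <- survnn.default(parts$x, parts$time, parts$status, ...)
  fit$formula <- formula
  fit
}

#' @rdname survnn
#' @export
survnn.default <- function(x, time, status, n_bag = 100, seed = NULL, ...) {
  x <- as.matrix(x)
  status <- as.integer(status)
  check_survdata(x, time, status)
  if (sum(status) < 2) stop("training data must contain at least 2 events")
  stopifnot(n_bag >= 1)
  if (is.null(seed)) seed <- sample.int(.Machine$integer.max, 1)
  set.seed(seed)
  member_seeds <- sample.int(.Machine$integer.max - 1L, n_bag)

  members <- vector("list", n_bag)
  oob_ll <- rep(NA_real_, n_bag)
  dropped <- 0L
  for (b in seq_len(n_bag)) {
    split <- bootstrap_split(nrow(x), status = status)
    fit_b <- tryCatch(
      coxnn.default(x[split$in_bag, , drop = FALSE], time[split$in_bag],
                    status[split$in_bag], seed = member_seeds[b], ...),
      error = function(e) NULL)
    if (is.null(fit_b)) { dropped <- dropped + 1L; next }
    # re-center on the full training set so that every aggregate of members
    # (any q) keeps a zero mean risk over the data the ensemble was fit to
    fit_b$offset <- mean(cpp_forward(fit_b$weights, fit_b$biases, x))
    members[[b]] <- fit_b
    oob <- split$out_of_bag
    oob_ll[b] <- if (sum(status[oob]) >= 1)
      oob_score(fit_b, x[oob, , drop = FALSE], time[oob], status[oob])
    else NA_real_  # flagged: ranked last
  }
  keep <- !vapply(members, is.null, logical(1))
  if (dropped > 0)
    warning(sprintf("%d degenerate bootstrap member(s) dropped", dropped))
  members <- members[keep]
  oob_ll <- oob_ll[keep]
  if (length(members) == 0) stop("all bootstrap members failed")

  # rank best-fit-first; unscoreable members last; ties by member index
  ord <- order(-oob_ll, seq_along(oob_ll), na.last = TRUE)
  pred_train <- vapply(members[ord], function(m) predict(m, x),
                       numeric(nrow(x)))
  sel <- select_q_opt(pred_train, time, status)

  risk_train <- rowMeans(pred_train[, seq_len(sel$q_opt), drop = FALSE])
  fit <- structure(list(members = members, oob_loglik = oob_ll, order = ord,
                        q_opt = sel$q_opt, q_loss = sel$loss,
                        n_bag = length(members), seed = as.integer(seed),
                        feature_names = colnames(x),
                        baseline = breslow_cumhaz(risk_train, time, status)),
                   class = "survnn")
  fit
}

#' @export
print.survnn <- function(x, ...) {
  cat(sprintf("Bagged Cox network ensemble: B = %d members, q_opt = %d\n",
              x$n_bag, x$q_opt))
  cat(sprintf("  OOB log partial likelihood: best %.4f, worst %.4f\n",
              max(x$oob_loglik, na.rm = TRUE), min(x$oob_loglik, na.rm = TRUE)))
  invisible(x)
}

#' @export
summary.survnn <- function(object, ...) {
  cat(sprintf("survnn ensemble, B = %d, q_opt = %d (training loss %.5f at q_opt, %.5f at q = B)\n",
              object$n_bag, object$q_opt, object$q_loss[object$q_opt],
              object$q_loss[object$n_bag]))
  print(data.frame(rank = seq_along(object$order),
                   member = object$order,
                   oob_loglik = object$oob_loglik[object$order],
                   used = seq_along(object$order) <= object$q_opt))
  invisible(object)
}

#' @rdname predict.coxnn
#' @export
predict.survnn <- function(object, newdata, ...) {
  x <- extract_features(newdata, object$feature_names)
  top <- object$members[object$order[seq_len(object$q_opt)]]
  preds <- vapply(top, function(m) predict(m, x), numeric(nrow(x)))
  rowMeans(matrix(preds, nrow = nrow(x)))
}

#' @export
refit.survnn <- function(object, x, time, status, seed = object$seed, ...) {
  m1 <- object$members[[1]]
  survnn.default(x, time, status, n_bag = object$n_bag, seed = seed,
                 hidden = m1$config$hidden, l1 = m1$config$l1,
                 learn_rate = m1$config$learn_rate,
                 batch_size = m1$config$batch_size, epochs = m1$config$epochs)
}

#' Bootstrap resample with out-of-bag complement
#'
#' Draws `n` indices with replacement; the out-of-bag set is the complement.
#' When `status` is supplied, splits whose OOB set carries fewer than two
#' events are redrawn (such a member could not be scored).
#'
#' @param n number of subjects.
#' @param status optional 0/1 event indicators used for the OOB-event check.
#' @param max_tries redraw limit.
#' @return list with `in_bag` (length `n`, with replacement) and `out_of_bag`.
#' @export
bootstrap_split <- function(n, status = NULL, max_tries = 100) {
  stopifnot(n >= 2)
  for (k in seq_len(max_tries)) {
    in_bag <- sample.int(n, n, replace = TRUE)
    oob <- setdiff(seq_len(n), in_bag)
    if (is.null(status) || sum(status[oob]) >= 2)
      return(list(in_bag = in_bag, out_of_bag = oob))
  }
  stop("could not draw a bootstrap split with >= 2 out-of-bag events")
}

#' Out-of-bag performance score of a fitted risk model
#'
#' Mean out-of-bag log partial likelihood with OOB-internal risk sets (the
#' negative of [neg_partial_loglik()] on the OOB subjects): higher is better.
#' Members of an ensemble are ranked by this score, best first.
#'
#' @param model a fitted risk model with a `predict` method.
#' @param x,time,status the out-of-bag subjects.
#' @return a single numeric score.
#' @export
oob_score <- function(model, x, time, status) {
  -neg_partial_loglik(predict(model, x), time, status)
}

#' Choose how many ranked members to aggregate
#'
#' For each `q` the ensemble prediction is the running mean of the first `q`
#' columns of `pred` (members in ranked order); returns the smallest `q`
#' minimizing the training negative mean partial log-likelihood.
#'
#' @param pred n x B matrix of member risk predictions, columns ranked
#'   best-fit-first.
#' @param time,status training outcomes.
#' @return list with `q_opt` and the per-`q` `loss` vector.
#' @export
select_q_opt <- function(pred, time, status) {
  pred <- as.matrix(pred)
  B <- ncol(pred)
  loss <- numeric(B)
  run <- numeric(nrow(pred))
  for (q in seq_len(B)) {
    run <- run + (pred[, q] - run) / q
    loss[q] <- neg_partial_loglik(run, time, status)
  }
  list(q_opt = which.min(loss), loss = loss)
}
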