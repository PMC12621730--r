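#' Permute one feature column
#'
#' Returns a copy of `x` with column `j` shuffled by a uniform random
#' permutation (drawn from the current RNG); all other columns are untouched.
#'
#' @param x feature matrix.
#' @param j column index.
#' @return matrix of the same shape.
#' @export
permute_feature <- function(x, j) {
  x <- as.matrix(x)
  if (j < 1 || j > ncol(x)) stop("column index out of range")
  x[, j] <- x[sample.int(nrow(x)), j]
  x
}

#' Per-fold permutation importance of one feature
#'
#' For `n_perm` independent permutations of column `j` of the validation
#' features, recomputes the model's risks and returns the drop in concordance,
#' \eqn{\Delta = C(\hat\xi) - C(\hat\xi_{perm})}. All permuted copies are
#' scored in one batched `predict` call, so the model is touched only through
#' its risk predictions.
#'
#' @param model fitted risk model (anything with a `predict` method mapping
#'   feature rows to risks).
#' @param x,time,status validation data, disjoint from the data `model` was
#'   fitted on.
#' @param j feature column index.
#' @param n_perm number of repeated permutations (R).
#' @param ties tie rule for [c_index()].
#' @return numeric vector of length `n_perm`.
#' @export
fold_importance <- function(model, x, time, status, j, n_perm = 100,
                            ties = "none") {
  x <- as.matrix(x)
  m <- nrow(x)
  c_orig <- c_index(predict(model, x), time, status, ties = ties)
  perms <- vapply(seq_len(n_perm), function(r) sample.int(m), integer(m))
  c_orig - perm_cindex(model, x, time, status, j, perms, ties)
}

# C-index of the model's risks under each permutation (columns of `perms`) of
# feature j. Ensembles of networks take a compiled path that reuses each
# member's first-layer pre-activations (concordance is invariant to the 1/q
# scaling, so the member sum stands in for the mean); any other model is
# scored through one batched predict() call on the row-stacked permuted
# copies.
perm_cindex <- function(model, x, time, status, j, perms, ties = "none") {
  m <- nrow(x)
  if (inherits(model, "survnn")) {
    top <- model$members[model$order[seq_len(model$q_opt)]]
    cper <- cpp_ensemble_perm_cindex(lapply(top, `[[`, "weights"),
                                     lapply(top, `[[`, "biases"),
                                     vapply(top, `[[`, numeric(1), "offset"),
                                     x, j, perms, as.numeric(time),
                                     as.integer(status), ties == "half")
    return(as.numeric(cper))
  }
  stacked <- x[rep(seq_len(m), ncol(perms)), , drop = FALSE]
  stacked[, j] <- x[as.vector(perms), j]
  risks <- matrix(predict(model, stacked), nrow = m)
  as.numeric(cpp_cindex_multi(risks, as.numeric(time), as.integer(status),
                              ties == "half"))
}

#' Cross-fitted permutation feature importance test
#'
#' Splits the data into `n_folds` folds (stratified by event status so every
#' fold holds events); for each fold, refits the model on the complement and
#' computes [fold_importance()] for every feature with `n_perm` repeated
#' permutations on the held-out fold. Per feature `j`, the retained
#' `B * R` raw values (`B = n_folds`, `R = n_perm`) are averaged into
#' \eqn{\hat\Delta_j} and their sample variance \eqn{\widehat{Var}_j}
#' (divisor `BR - 1`) standardizes it into a z-type statistic whose one-sided
#' upper-tail normal probability is the p-value: importance is meaningful only
#' as a positive degradation.
#'
#' Three denominators are available, because raw values within a fold share
#' the fold's fitted model and are strongly correlated:
#' * `var_type = "fold"` (default): \eqn{\Lambda_j = \hat\Delta_j /
#'   \sqrt{\widehat{Var}_j / B}}. The B cross-fitting folds are treated as the
#'   independent units and each fold mean's variance is bounded by the pooled
#'   sample variance. Calibration simulations under the null (see the package
#'   vignette) show near-nominal type I error for this choice.
#' * `var_type = "raw"`: \eqn{\hat\Delta_j / \sqrt{\widehat{Var}_j}}, no
#'   scaling; strongly conservative since the permutation noise that dominates
#'   \eqn{\widehat{Var}_j} is averaged away in \eqn{\hat\Delta_j}.
#' * `var_type = "mean"`: \eqn{\hat\Delta_j / \sqrt{\widehat{Var}_j / (BR)}},
#'   the i.i.d. standard error of the mean; strongly anticonservative because
#'   the BR values are not independent.
#'
#' The test is model-agnostic: it touches the model only through [refit()] and
#' `predict`, so any risk model (e.g. [coxlin()] or [survnn()]) plugs in.
#'
#' @param object a fitted risk model (template: its hyperparameters are reused
#'   when refitting on each fold complement), or a function
#'   `f(x, time, status)` returning a fitted model.
#' @param data data frame with feature columns plus `time` and `status`, or a
#'   list as produced internally; alternatively pass `x`, `time`, `status`.
#' @param x,time,status data supplied directly instead of `data`.
#' @param n_folds number of cross-fitting folds (B).
#' @param n_perm permutations per fold and feature (R).
#' @param alpha significance cutoff for the `selected` flag.
#' @param var_type `"fold"`, `"raw"` or `"mean"`; see above.
#' @param ties tie rule for the concordance index.
#' @param seed integer seed; fold assignment and permutations derive from it.
#' @return An object of class `"permfit"`: a data frame `importance` with
#'   columns `feature`, `delta`, `var`, `lambda`, `p_value`, `selected`, plus
#'   the raw `p x B x R` array `raw` and the configuration.
#' @examples
#' sim <- simulate_survdata(scenario = 1, n = 400, seed = 5)
#' fit <- coxlin(Surv(time, status) ~ ., data = sim$train)
#' pf <- permfit(fit, sim$train, n_folds = 3, n_perm = 10, seed = 5)
#' head(pf$importance)
#' @export
permfit <- function(object, data = NULL, x = NULL, time = NULL, status = NULL,
                    n_folds = 5, n_perm = 100, alpha = 0.05,
                    var_type = c("fold", "raw", "mean"), ties = "none",
                    seed = NULL) {
  var_type <- match.arg(var_type)
  stopifnot(n_folds >= 2, n_perm >= 1, alpha > 0, alpha < 1)
  if (!is.null(data)) {
    parts <- surv_parts(data)
    x <- parts$x; time <- parts$time; status <- parts$status
  }
  x <- as.matrix(x)
  status <- as.integer(status)
  check_survdata(x, time, status)
  if (!is.null(seed)) set.seed(seed)

  n <- nrow(x)
  p <- ncol(x)
  feat <- colnames(x)
  if (is.null(feat)) feat <- paste0("V", seq_len(p))
  folds <- stratified_folds(status, n_folds)

  fit_fold <- function(idx) {
    if (is.function(object))
      object(x[idx, , drop = FALSE], time[idx], status[idx])
    else
      refit(object, x[idx, , drop = FALSE], time[idx], status[idx])
  }

  raw <- array(NA_real_, dim = c(p, n_folds, n_perm),
               dimnames = list(feat, NULL, NULL))
  for (b in seq_len(n_folds)) {
    val <- which(folds == b)
    xval <- x[val, , drop = FALSE]
    tval <- time[val]
    sval <- status[val]
    m <- length(val)
    model_b <- fit_fold(which(folds != b))
    c_orig <- c_index(predict(model_b, xval), tval, sval, ties = ties)
    fast <- inherits(model_b, "survnn")
    # one row-stacked scratch matrix per fold; each feature writes and then
    # restores its own column in place
    if (!fast) stacked <- xval[rep(seq_len(m), n_perm), , drop = FALSE]
    for (j in seq_len(p)) {
      perms <- vapply(seq_len(n_perm), function(r) sample.int(m), integer(m))
      if (fast) {
        cper <- perm_cindex(model_b, xval, tval, sval, j, perms, ties)
      } else {
        cpp_set_column(stacked, j, xval[as.vector(perms), j])
        risks <- matrix(predict(model_b, stacked), nrow = m)
        cpp_set_column(stacked, j, rep(xval[, j], n_perm))
        cper <- as.numeric(cpp_cindex_multi(risks, as.numeric(tval),
                                            as.integer(sval), ties == "half"))
      }
      raw[j, b, ] <- c_orig - cper
    }
  }

  delta <- apply(raw, 1, mean)
  v <- apply(raw, 1, function(m) stats::var(as.vector(m)))  # divisor BR - 1
  denom <- switch(var_type,
                  fold = sqrt(v / n_folds),
                  raw = sqrt(v),
                  mean = sqrt(v / (n_folds * n_perm)))
  lambda <- ifelse(denom > 0, delta / denom, 0)
  p_value <- stats::pnorm(lambda, lower.tail = FALSE)

  structure(list(importance = data.frame(feature = feat, delta = delta,
                                         var = v, lambda = lambda,
                                         p_value = p_value,
                                         selected = p_value <= alpha,
                                         row.names = NULL),
                 raw = raw,
                 config = list(n_folds = n_folds, n_perm = n_perm,
                               alpha = alpha, var_type = var_type,
                               ties = ties, seed = seed)),
            class = "permfit")
}

#' @export
print.permfit <- function(x, digits = 4, ...) {
  cat(sprintf("Permutation feature importance test (%d folds x %d permutations, var = \"%s\")\n",
              x$config$n_folds, x$config$n_perm, x$config$var_type))
  imp <- x$importance[order(x$importance$p_value, -x$importance$delta), ]
  print(format(imp, digits = digits), row.names = FALSE)
  cat(sprintf("%d of %d features selected at p <= %g\n",
              sum(x$importance$selected), nrow(x$importance), x$config$alpha))
  invisible(x)
}

#' Refit a model on the features selected by the importance test
#'
#' Convenience driver: keeps the features with `p_value <= alpha`, refits the
#' template model on them, and returns the reduced fit.
#'
#' @param object fitted model template (or fitter function, as in [permfit()]).
#' @param result a `"permfit"` object.
#' @param data data frame with feature, `time` and `status` columns.
#' @return the refitted model on the selected features.
#' @export
refit_selected <- function(object, result, data) {
  stopifnot(inherits(result, "permfit"))
  keep <- result$importance$feature[result$importance$selected]
  if (length(keep) == 0) stop("no features were selected")
  parts <- surv_parts(data)
  xs <- parts$x[, keep, drop = FALSE]
  if (is.function(object)) object(xs, parts$time, parts$status)
  else refit(object, xs, parts$time, parts$status)
}

# Random near-equal fold assignment, stratified by event indicator so each
# fold carries events; internal.
stratified_folds <- function(status, n_folds) {
  n <- length(status)
  folds <- integer(n)
  for (s in unique(status)) {
    idx <- which(status == s)
    folds[idx] <- sample(rep_len(seq_len(n_folds), length(idx)))
  }
  folds
}
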