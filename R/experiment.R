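#' Truly important features of a simulation scenario
#'
#' The features entering the scenario's risk function: scenario 1 uses
#' `X1, X{p0+1}, X{2p0+1}, X{3p0+1}, Z1`; scenario 2 additionally involves
#' `Z2` through the `X1 * Z2` interaction.
#'
#' @param scenario 1 or 2.
#' @param p0 block size (default 10).
#' @return character vector of feature names.
#' @export
important_features <- function(scenario, p0 = 10) {
  stopifnot(scenario %in% c(1, 2))
  base <- c("X1", paste0("X", p0 + 1), paste0("X", 2 * p0 + 1),
            paste0("X", 3 * p0 + 1), "Z1")
  if (scenario == 2) c(base, "Z2") else base
}

#' Rank sum of the important features
#'
#' Ranks all features by importance score, descending (rank 1 = most
#' important, ties broken by feature position), and sums the ranks of the
#' named important set. When the important set occupies the top ranks the sum
#' attains its oracle lower bound \eqn{|S|(|S|+1)/2}.
#'
#' @param scores named numeric vector of per-feature importance scores.
#' @param important character vector naming the truly important features.
#' @return integer rank sum.
#' @export
rank_sum <- function(scores, important) {
  stopifnot(!is.null(names(scores)), all(important %in% names(scores)))
  ranks <- order(order(-scores, seq_along(scores)))
  names(ranks) <- names(scores)
  sum(ranks[important])
}

#' Replicated feature-selection experiment on simulated data
#'
#' For each replication: generate a fresh scenario dataset, run the method's
#' selection procedure, and record which features are declared important
#' (p-value at most `alpha`) plus the rank sum of the truly important set.
#' Methods: `"cox"` fits the linear Cox model on all features and uses
#' two-sided Wald p-values (ranking by `|z|`); `"permcox"` runs [permfit()]
#' with the linear Cox fitter; `"permnn"` runs [permfit()] with the bagged
#' network fitter ([survnn()]). Permutation methods rank by the importance
#' estimate \eqn{\hat\Delta_j}.
#'
#' @param scenario,rho,n,alpha_effect generator settings passed to
#'   [simulate_survdata()] (`alpha_effect` defaults to `1000 / n`).
#' @param method `"cox"`, `"permcox"` or `"permnn"`.
#' @param n_reps number of replications.
#' @param seed master seed; per-replication seeds derive from it.
#' @param alpha significance cutoff.
#' @param n_folds,n_perm,var_type [permfit()] settings.
#' @param n_bag,hidden,epochs,l1,learn_rate,batch_size network settings for
#'   `method = "permnn"`. The default `n_bag = 10` is a reduced-scale setting
#'   for replicated runs; single fits default to 100 members.
#' @param checkpoint optional CSV path; per-replication rows are appended as
#'   they complete and an interrupted run resumes from it.
#' @return An object of class `"experiment_summary"` with per-feature rejection
#'   frequencies, `avg_power` (mean over the truly important set), `type1`
#'   (mean over the null features) and `avg_rank_sum`.
#' @export
run_experiment <- function(scenario = 1, rho = 0, n = 1000,
                           method = c("cox", "permcox", "permnn"),
                           n_reps = 100, seed = 1, alpha = 0.05,
                           alpha_effect = 1000 / n,
                           n_folds = 5, n_perm = 100, var_type = "fold",
                           n_bag = 10, hidden = c(50, 20), epochs = 200,
                           l1 = 1e-4, learn_rate = 1e-3, batch_size = 128,
                           checkpoint = NULL) {
  method <- match.arg(method)
  stopifnot(n_reps >= 1)
  set.seed(seed)
  rep_seeds <- sample.int(.Machine$integer.max - 1L, n_reps)

  done <- NULL
  if (!is.null(checkpoint) && file.exists(checkpoint)) {
    done <- utils::read.csv(checkpoint)
  }

  rows <- vector("list", n_reps)
  failed <- 0L
  for (r in seq_len(n_reps)) {
    if (!is.null(done) && r <= nrow(done)) {
      rows[[r]] <- done[r, ]
      next
    }
    res <- tryCatch(
      one_replication(scenario, rho, n, method, rep_seeds[r], alpha,
                      alpha_effect, n_folds, n_perm, var_type, n_bag,
                      hidden, epochs, l1, learn_rate, batch_size),
      error = function(e) {
        warning(sprintf("replication %d failed: %s", r, conditionMessage(e)))
        NULL
      })
    if (is.null(res)) { failed <- failed + 1L; next }
    rows[[r]] <- res
    if (!is.null(checkpoint))
      utils::write.csv(do.call(rbind, rows[!vapply(rows, is.null, logical(1))]),
                       checkpoint, row.names = FALSE)
  }
  rows <- rows[!vapply(rows, is.null, logical(1))]
  if (length(rows) == 0) stop("all replications failed")
  tab <- do.call(rbind, rows)

  imp <- important_features(scenario)
  feat_cols <- setdiff(names(tab), "rank_sum")
  power <- colMeans(tab[, feat_cols, drop = FALSE])
  null_feat <- setdiff(feat_cols, imp)

  structure(list(method = method, scenario = scenario, rho = rho, n = n,
                 n_reps = length(rows), n_failed = failed,
                 per_feature_power = power,
                 avg_power = mean(power[imp]),
                 type1 = mean(power[null_feat]),
                 avg_rank_sum = mean(tab$rank_sum),
                 important = imp, seed = seed,
                 settings = list(alpha = alpha, alpha_effect = alpha_effect,
                                 n_folds = n_folds, n_perm = n_perm,
                                 var_type = var_type, n_bag = n_bag,
                                 hidden = hidden, epochs = epochs, l1 = l1,
                                 learn_rate = learn_rate,
                                 batch_size = batch_size)),
            class = "experiment_summary")
}

one_replication <- function(scenario, rho, n, method, rep_seed, alpha,
                            alpha_effect, n_folds, n_perm, var_type, n_bag,
                            hidden, epochs, l1, learn_rate, batch_size) {
  sim <- simulate_survdata(scenario = scenario, n = n, test_n = 0, rho = rho,
                           alpha = alpha_effect, seed = rep_seed)
  parts <- surv_parts(sim$train)
  imp <- important_features(scenario, p0 = sim$p0)

  if (method == "cox") {
    fit <- coxlin.default(parts$x, parts$time, parts$status)
    rejected <- fit$wald_p <= alpha
    scores <- abs(fit$wald_z)
  } else {
    fitter <- if (method == "permcox") {
      function(x, time, status) coxlin.default(x, time, status)
    } else {
      function(x, time, status)
        survnn.default(x, time, status, n_bag = n_bag, hidden = hidden,
                       epochs = epochs, l1 = l1, learn_rate = learn_rate,
                       batch_size = batch_size, seed = rep_seed + 1L)
    }
    pf <- permfit(fitter, x = parts$x, time = parts$time,
                  status = parts$status, n_folds = n_folds, n_perm = n_perm,
                  alpha = alpha, var_type = var_type, seed = rep_seed)
    rejected <- pf$importance$selected
    scores <- stats::setNames(pf$importance$delta, pf$importance$feature)
  }
  names(rejected) <- colnames(parts$x)
  row <- as.data.frame(as.list(as.integer(rejected)))
  names(row) <- colnames(parts$x)
  row$rank_sum <- rank_sum(stats::setNames(as.numeric(scores),
                                           colnames(parts$x)), imp)
  row
}

#' @export
print.experiment_summary <- function(x, ...) {
  cat(sprintf("Feature-selection experiment: method = %s, scenario %d, rho = %g, n = %d (%d reps%s)\n",
              x$method, x$scenario, x$rho, x$n, x$n_reps,
              if (x$n_failed > 0) sprintf(", %d failed", x$n_failed) else ""))
  for (f in x$important)
    cat(sprintf("  %-5s rejection rate: %.3f\n", f, x$per_feature_power[f]))
  cat(sprintf("  Avg power:    %.3f\n", x$avg_power))
  cat(sprintf("  Type I error: %.3f\n", x$type1))
  cat(sprintf("  Avg rank sum: %.2f (oracle %d)\n", x$avg_rank_sum,
              sum(seq_along(x$important))))
  invisible(x)
}

#' Write an experiment summary as a table-shaped CSV
#'
#' One row per feature rejection frequency plus summary rows `Avg Power`,
#' `Type I Error` and `Avg Rank Sum`.
#'
#' @param x an `"experiment_summary"`.
#' @param path output CSV path.
#' @export
write_experiment_csv <- function(x, path) {
  stopifnot(inherits(x, "experiment_summary"))
  rows <- data.frame(variable = c(x$important, "Avg Power", "Type I Error",
                                  "Avg Rank Sum"),
                     value = c(unname(x$per_feature_power[x$important]),
                               x$avg_power, x$type1, x$avg_rank_sum))
  rows$method <- x$method
  rows$scenario <- x$scenario
  rows$rho <- x$rho
  rows$n <- x$n
  rows$n_reps <- x$n_reps
  utils::write.csv(rows, path, row.names = FALSE)
  invisible(path)
}
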