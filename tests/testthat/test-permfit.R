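test_that("permuting a column preserves its multiset and nothing else", {
  set.seed(70)
  x <- matrix(rnorm(30), 10, 3)
  px <- permute_feature(x, 2)
  expect_equal(sort(px[, 2]), sort(x[, 2]))
  expect_identical(px[, c(1, 3)], x[, c(1, 3)])
  expect_identical(permute_feature(x[1, , drop = FALSE], 2),
                   x[1, , drop = FALSE])
  expect_error(permute_feature(x, 4), "out of range")
})

test_that("a feature the model ignores has exactly zero importance", {
  set.seed(71)
  d <- linear_ph_data(60, beta = c(1, 0), seed = 71)
  fit <- coxlin(d$x, d$time, d$status)
  fit$beta[2] <- 0  # force the model to ignore feature 2 on the zero path
  vals <- fold_importance(fit, d$x, d$time, d$status, j = 2, n_perm = 20)
  expect_identical(vals, rep(0, 20))
})

test_that("permuting a perfectly concordant single feature cannot help", {
  # 4 subjects, risk strictly anti-monotone in time: original C = 1
  x <- matrix(c(4, 3, 2, 1), 4, 1, dimnames = list(NULL, "V1"))
  tm <- c(1, 2, 3, 4)
  st <- rep(1L, 4)
  # separation: the likelihood has no finite maximizer, only the risk
  # ordering matters here
  fit <- suppressWarnings(coxlin(x, tm, st))
  expect_equal(c_index(predict(fit, x), tm, st), 1)
  set.seed(72)
  vals <- fold_importance(fit, x, tm, st, j = 1, n_perm = 50)
  expect_true(all(vals >= 0))
})

test_that("pure-noise features have mean importance near zero", {
  # independent (fit, validation) pairs; 25 permutations each, 500 in total.
  # The pair-level means are the independent units for the Monte-Carlo SE.
  pair_means <- vapply(1:20, function(k) {
    fit_d <- linear_ph_data(400, beta = c(0.8, 0, 0), seed = 730 + k)
    val_d <- linear_ph_data(400, beta = c(0.8, 0, 0), seed = 930 + k)
    fit <- coxlin(fit_d$x, fit_d$time, fit_d$status)
    set.seed(73 + k)
    mean(fold_importance(fit, val_d$x, val_d$time, val_d$status, j = 3,
                         n_perm = 25))
  }, numeric(1))
  mc_se <- sd(pair_means) / sqrt(length(pair_means))
  expect_lt(abs(mean(pair_means)), 3 * mc_se)
})

test_that("aggregation identities hold exactly and runs are deterministic", {
  sim <- simulate_survdata(scenario = 1, n = 200, test_n = 0, p0 = 2,
                           seed = 74)
  fitter <- function(x, time, status) coxlin(x, time, status)
  pf <- permfit(fitter, sim$train, n_folds = 3, n_perm = 7, seed = 74)

  expect_equal(dim(pf$raw), c(10, 3, 7))
  expect_equal(pf$importance$delta, apply(pf$raw, 1, mean),
               ignore_attr = TRUE)
  expect_equal(pf$importance$var,
               apply(pf$raw, 1, function(m) var(as.vector(m))),
               ignore_attr = TRUE, tolerance = 1e-12)
  expect_equal(pf$importance$lambda,
               pf$importance$delta / sqrt(pf$importance$var / 3),
               ignore_attr = TRUE)
  expect_equal(pf$importance$p_value, pnorm(pf$importance$lambda,
                                            lower.tail = FALSE),
               ignore_attr = TRUE)

  pf2 <- permfit(fitter, sim$train, n_folds = 3, n_perm = 7, seed = 74)
  expect_identical(pf$importance, pf2$importance)
  expect_identical(pf$raw, pf2$raw)
})

test_that("the test is model-agnostic: template objects and fitters agree", {
  sim <- simulate_survdata(scenario = 1, n = 200, test_n = 0, p0 = 2,
                           seed = 75)
  template <- coxlin(Surv(time, status) ~ ., data = sim$train)
  pf_obj <- permfit(template, sim$train, n_folds = 3, n_perm = 5, seed = 75)
  pf_fun <- permfit(function(x, time, status) coxlin(x, time, status),
                    sim$train, n_folds = 3, n_perm = 5, seed = 75)
  expect_equal(pf_obj$importance, pf_fun$importance)
})

test_that("network-based test detects interactions the linear test misses", {
  sim <- simulate_survdata(scenario = 2, n = 1000, test_n = 0, seed = 76)
  pf_cox <- permfit(function(x, time, status) coxlin(x, time, status),
                    sim$train, n_folds = 5, n_perm = 30, seed = 76)
  fitter_nn <- function(x, time, status)
    survnn(x, time, status, n_bag = 5, epochs = 100, seed = 77)
  pf_nn <- permfit(fitter_nn, sim$train, n_folds = 5, n_perm = 30, seed = 76)

  inter <- c("X21", "X31")  # pure interaction pair, invisible to a linear fit
  p_cox <- pf_cox$importance$p_value[pf_cox$importance$feature %in% inter]
  p_nn <- pf_nn$importance$p_value[pf_nn$importance$feature %in% inter]
  expect_true(all(p_nn <= 0.05))
  expect_true(all(p_nn < p_cox))
})

test_that("refitting on selected features reduces the model", {
  sim <- simulate_survdata(scenario = 1, n = 400, test_n = 0, seed = 78)
  template <- coxlin(Surv(time, status) ~ ., data = sim$train)
  pf <- permfit(template, sim$train, n_folds = 3, n_perm = 20, seed = 78)
  reduced <- refit_selected(template, pf, sim$train)
  expect_s3_class(reduced, "coxlin")
  expect_equal(length(reduced$beta), sum(pf$importance$selected))
})

test_that("raw and mean variance conventions are available and ordered", {
  sim <- simulate_survdata(scenario = 1, n = 300, test_n = 0, p0 = 2,
                           seed = 79)
  fitter <- function(x, time, status) coxlin(x, time, status)
  p_fold <- permfit(fitter, sim$train, n_folds = 3, n_perm = 10, seed = 79)
  p_raw <- permfit(fitter, sim$train, n_folds = 3, n_perm = 10, seed = 79,
                   var_type = "raw")
  p_mean <- permfit(fitter, sim$train, n_folds = 3, n_perm = 10, seed = 79,
                    var_type = "mean")
  # same raw values, increasingly aggressive standardization
  expect_identical(p_fold$raw, p_raw$raw)
  pos <- p_fold$importance$delta > 0
  expect_true(all(p_raw$importance$lambda[pos] <=
                    p_fold$importance$lambda[pos]))
  expect_true(all(p_fold$importance$lambda[pos] <=
                    p_mean$importance$lambda[pos]))
})
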