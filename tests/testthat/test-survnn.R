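test_that("bootstrap splits have the classical out-of-bag fraction", {
  set.seed(20)
  n <- 1000
  fracs <- replicate(200, length(bootstrap_split(n)$out_of_bag) / n)
  expect_lt(abs(mean(fracs) - exp(-1)), 0.02)

  sp <- bootstrap_split(n)
  expect_length(sp$in_bag, n)
  expect_setequal(union(sp$in_bag, sp$out_of_bag), seq_len(n))

  # with status supplied, the OOB set always carries >= 2 events
  st <- c(rep(1L, 5), rep(0L, 15))
  for (k in 1:20) expect_gte(sum(st[bootstrap_split(20, st)$out_of_bag]), 2)
})

test_that("oob score equals the hand-enumerated nested-risk-set value", {
  d <- tiny_surv(5)
  const_model <- structure(list(), class = "const_risk")
  assign("predict.const_risk",
         function(object, newdata, ...) rep(1.4, nrow(newdata)),
         envir = globalenv())
  on.exit(rm("predict.const_risk", envir = globalenv()))
  # all events, distinct times, constant risk: contributions -log(5..1)
  expect_equal(oob_score(const_model, d$x, d$time, d$status),
               -mean(log(5:1)))
})

test_that("oob score is shift invariant and favors the true risk", {
  set.seed(21)
  sim <- simulate_survdata(scenario = 1, n = 2000, test_n = 0, seed = 21)
  parts <- survperm:::surv_parts(sim$train)
  true_xi <- linear_predictor(1, parts$x, alpha = 1)

  shift_model <- function(off) {
    m <- structure(list(off = off, xi = true_xi), class = "fixed_risk")
    m
  }
  assign("predict.fixed_risk",
         function(object, newdata, ...) object$xi + object$off,
         envir = globalenv())
  on.exit(rm("predict.fixed_risk", envir = globalenv()))
  s0 <- oob_score(shift_model(0), parts$x, parts$time, parts$status)
  s7 <- oob_score(shift_model(7), parts$x, parts$time, parts$status)
  expect_equal(s0, s7)

  rand_model <- structure(list(off = 0, xi = sample(true_xi)),
                          class = "fixed_risk")
  expect_gt(s0, oob_score(rand_model, parts$x, parts$time, parts$status))
})

test_that("q selection minimizes the training loss with smallest-q ties", {
  d <- tiny_surv(10, seed = 30)
  # B = 1
  one <- select_q_opt(matrix(rnorm(10)), d$time, d$status)
  expect_equal(one$q_opt, 1L)

  # identical members: loss constant in q, tie broken at q = 1
  same <- matrix(rep(rnorm(10), 4), ncol = 4)
  expect_equal(select_q_opt(same, d$time, d$status)$q_opt, 1L)

  # argmin property: loss at q_opt <= loss at q = B
  set.seed(31)
  pred <- matrix(rnorm(50), 10, 5)
  sel <- select_q_opt(pred, d$time, d$status)
  expect_lte(sel$loss[sel$q_opt], sel$loss[5])
  # running means recompute correctly
  expect_equal(sel$loss[3],
               neg_partial_loglik(rowMeans(pred[, 1:3]), d$time, d$status))
})

test_that("ensemble fit is deterministic, ranked and centered", {
  sim <- simulate_survdata(scenario = 2, n = 400, test_n = 150, seed = 40)
  fit <- survnn(Surv(time, status) ~ ., data = sim$train, n_bag = 5,
                hidden = c(16, 8), epochs = 40, seed = 40)
  fit2 <- survnn(Surv(time, status) ~ ., data = sim$train, n_bag = 5,
                 hidden = c(16, 8), epochs = 40, seed = 40)
  expect_identical(fit$q_opt, fit2$q_opt)
  expect_identical(predict(fit, sim$test), predict(fit2, sim$test))

  # ranking is a permutation sorted by OOB fit, best first
  expect_setequal(fit$order, seq_len(5))
  expect_identical(order(-fit$oob_loglik, seq_len(5)), fit$order)

  # centering inherited from members
  expect_lt(abs(mean(predict(fit, sim$train))), 1e-6)

  # with q_opt forced to B the prediction is the plain bagged average
  all_members <- vapply(fit$members, function(m) predict(m, sim$test),
                        numeric(nrow(sim$test)))
  full <- fit
  full$q_opt <- 5L
  expect_equal(predict(full, sim$test), rowMeans(all_members),
               tolerance = 1e-12)
})

test_that("filtered ensemble is at least as good as its worst member", {
  sim <- simulate_survdata(scenario = 2, n = 600, test_n = 300, seed = 41)
  fit <- survnn(Surv(time, status) ~ ., data = sim$train, n_bag = 5,
                epochs = 60, seed = 41)
  member_ci <- vapply(fit$members, function(m)
    c_index(predict(m, sim$test), sim$test$time, sim$test$status), numeric(1))
  ens_ci <- c_index(predict(fit, sim$test), sim$test$time, sim$test$status)
  expect_gte(ens_ci, min(member_ci))
})

test_that("ensemble beats the linear model on non-linear data", {
  sim <- simulate_survdata(scenario = 2, n = 1000, test_n = 400, seed = 31)
  fit <- survnn(Surv(time, status) ~ ., data = sim$train, n_bag = 5,
                epochs = 100, seed = 31)
  cl <- coxlin(Surv(time, status) ~ ., data = sim$train)
  ci_nn <- c_index(predict(fit, sim$test), sim$test$time, sim$test$status)
  ci_cox <- c_index(predict(cl, sim$test), sim$test$time, sim$test$status)
  expect_gt(ci_nn, ci_cox)
})

test_that("ensemble survival curves use the Breslow baseline sensibly", {
  sim <- simulate_survdata(scenario = 2, n = 300, test_n = 80, seed = 42)
  fit <- survnn(Surv(time, status) ~ ., data = sim$train, n_bag = 3,
                hidden = c(8, 4), epochs = 30, seed = 42)
  S <- predict_survival(fit, sim$test, times = c(0, 1, 2, 4))
  expect_equal(S[, 1], rep(1, 80))
  expect_true(all(S >= 0 & S <= 1))
  expect_true(all(apply(S, 1, function(r) all(diff(r) <= 0))))
  v <- integrated_brier(fit, sim$test)
  expect_gt(v, 0)
  expect_lt(v, 0.5)
})
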