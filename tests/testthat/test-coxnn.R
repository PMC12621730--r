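test_that("forward pass matches hand-computed values", {
  # zero network maps everything to 0
  w0 <- list(matrix(0, 3, 2), matrix(0, 1, 3))
  b0 <- list(rep(0, 3), 0)
  x <- matrix(rnorm(10), 5, 2)
  expect_equal(as.numeric(survperm:::cpp_forward(w0, b0, x)), rep(0, 5))

  # K = 1: ReLU(x) * 2 + 1
  w1 <- list(matrix(1, 1, 1), matrix(2, 1, 1))
  b1 <- list(0, 1)
  expect_equal(as.numeric(survperm:::cpp_forward(w1, b1, matrix(-3))), 1)
  expect_equal(as.numeric(survperm:::cpp_forward(w1, b1, matrix(2))), 5)

  # row-wise: each row's output depends only on that row
  set.seed(10)
  w <- list(matrix(rnorm(6), 3, 2), matrix(rnorm(3), 1, 3))
  b <- list(rnorm(3), rnorm(1))
  X <- matrix(rnorm(14), 7, 2)
  full <- as.numeric(survperm:::cpp_forward(w, b, X))
  rowwise <- vapply(seq_len(7), function(i)
    as.numeric(survperm:::cpp_forward(w, b, X[i, , drop = FALSE])), numeric(1))
  expect_equal(full, rowwise)

  expect_error(survperm:::cpp_forward(w, b, matrix(0, 2, 3)), "layer")
})

test_that("partial-likelihood loss matches hand values and brute force", {
  expect_equal(neg_partial_loglik(c(0, 0), time = c(1, 2), status = c(1, 1)),
               log(2) / 2)

  # single event: full risk set
  xi <- c(0.3, -1.2, 0.7)
  expect_equal(neg_partial_loglik(xi, time = c(1, 2, 3), status = c(1, 0, 0)),
               -(xi[1] - log(sum(exp(xi)))))

  # shift invariance
  set.seed(11)
  d <- tiny_surv(8)
  xi8 <- rnorm(8)
  expect_equal(neg_partial_loglik(xi8, d$time, d$status),
               neg_partial_loglik(xi8 + 5.7, d$time, d$status))

  # brute-force double loop on random instances, including tied times
  for (k in 1:20) {
    set.seed(100 + k)
    n <- sample(3:20, 1)
    tm <- sample(1:8, n, replace = TRUE) / 2
    st <- rbinom(n, 1, 0.6)
    if (sum(st) == 0) st[1] <- 1L
    xi <- rnorm(n, sd = 2)
    expect_equal(neg_partial_loglik(xi, tm, st),
                 negpll_bruteforce(xi, tm, st), tolerance = 1e-10)
  }

  expect_error(neg_partial_loglik(c(1, 2), c(1, 2), c(0, 0)), "no events")
})

test_that("loss gradient matches finite differences", {
  for (k in 1:5) {
    set.seed(200 + k)
    n <- 12
    tm <- sample(1:6, n, replace = TRUE)
    st <- rbinom(n, 1, 0.5)
    if (sum(st) == 0) st[1] <- 1L
    xi <- rnorm(n)
    g <- as.numeric(survperm:::cpp_negpll_grad(xi, tm, as.integer(st)))
    h <- 1e-6
    fd <- vapply(seq_len(n), function(i) {
      e <- numeric(n); e[i] <- h
      (neg_partial_loglik(xi + e, tm, st) -
         neg_partial_loglik(xi - e, tm, st)) / (2 * h)
    }, numeric(1))
    expect_equal(g, fd, tolerance = 1e-5)
  }
})

test_that("training learns an informative risk and is seed-reproducible", {
  sim <- simulate_survdata(scenario = 1, n = 1000, test_n = 300, seed = 42)
  fit <- coxnn(Surv(time, status) ~ ., data = sim$train, epochs = 100,
               seed = 1)
  ci <- c_index(predict(fit, sim$test), sim$test$time, sim$test$status)
  expect_gte(ci, 0.6)

  # centering constraint: mean fitted risk on training data is 0
  expect_lt(abs(mean(predict(fit, sim$train))), 1e-6)

  # determinism
  fit2 <- coxnn(Surv(time, status) ~ ., data = sim$train, epochs = 100,
                seed = 1)
  expect_identical(predict(fit, sim$test), predict(fit2, sim$test))

  # a different seed gives a different network
  fit3 <- coxnn(Surv(time, status) ~ ., data = sim$train, epochs = 100,
                seed = 2)
  expect_false(identical(predict(fit, sim$test), predict(fit3, sim$test)))
})

test_that("an overwhelming penalty collapses predictions to a constant", {
  sim <- simulate_survdata(scenario = 1, n = 300, test_n = 100, seed = 6)
  fit <- coxnn(Surv(time, status) ~ ., data = sim$train, epochs = 50,
               l1 = 1e3, seed = 3)
  risks <- predict(fit, sim$test)
  expect_lt(diff(range(risks)), 1e-4)
  # constant predictions score 0 under the strict tie rule
  expect_equal(c_index(rep(0, nrow(sim$train)), sim$train$time,
                       sim$train$status), 0)
})

test_that("training input is validated", {
  d <- tiny_surv()
  expect_error(coxnn(d$x, d$time, rep(0L, 6)), "2 events")
  expect_error(coxnn(d$x, c(d$time[-1], -1), d$status), "positive")
  expect_error(coxnn(d$x, d$time, d$status, batch_size = 1), "batch_size")
  expect_error(coxnn(d$x, d$time, d$status, hidden = integer(0)), "hidden")
})
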