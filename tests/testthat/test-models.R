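test_that("Huber loss matches its definition at and beyond the knot", {
  expect_equal(huber_loss(0, 1), 0)
  expect_equal(huber_loss(1, 1), 0.5)          # both branches agree at r = delta
  expect_equal(huber_loss(3, 1), 2.5)          # delta * (|r| - delta/2)
  expect_equal(huber_loss(-3, 1), 2.5)
  # continuity and matching one-sided slopes at the knot
  eps <- 1e-7
  expect_equal(huber_loss(1 + eps, 1) - huber_loss(1, 1), eps, tolerance = 1e-6)
  expect_equal(huber_loss(1, 1) - huber_loss(1 - eps, 1), eps, tolerance = 1e-6)
  # convexity on a grid
  r <- seq(-5, 5, by = 0.1)
  expect_true(all(diff(diff(huber_loss(r, 1.3))) > -1e-12))
  expect_error(huber_loss(1, 0), class = "chlorospec_domain_error")
})

test_that("Huber IRLS recovers exact and near-OLS solutions", {
  set.seed(51)
  X <- matrix(rnorm(80 * 3), 80, 3)
  beta <- c(4, 2, -1, 0.5)
  y_exact <- drop(cbind(1, X) %*% beta)
  m <- fit_robust_linear(X, y_exact)
  expect_equal(unname(m$state$coefficients), beta, tolerance = 1e-8)
  expect_true(m$training_summary$converged)
  # Gaussian noise, huge delta: coincides with OLS
  y <- y_exact + rnorm(80)
  m2 <- fit_robust_linear(X, y, delta = 1e6)
  ols <- unname(coef(lm(y ~ X)))
  expect_equal(unname(m2$state$coefficients), ols, tolerance = 1e-4)
  expect_error(fit_robust_linear(X[1:3, ], y[1:3]),
               class = "chlorospec_input_error")
  expect_error(fit_robust_linear(cbind(X, X[, 1]), y),
               class = "chlorospec_decomposition_error")
})

test_that("Huber IRLS agrees with an independent M-estimation route", {
  set.seed(52)
  X <- matrix(rnorm(200 * 3), 200, 3); colnames(X) <- paste0("x", 1:3)
  y <- drop(X %*% c(2, -1, 0.5)) + 1 + rnorm(200, sd = 0.5)
  y[1:10] <- y[1:10] + 30
  ours <- fit_robust_linear(X, y)
  ref <- MASS::rlm(y ~ X, psi = MASS::psi.huber, maxit = 200)
  expect_equal(unname(ours$state$coefficients), unname(coef(ref)),
               tolerance = 1e-3)
})

test_that("robust fitting resists a gross outlier better than OLS", {
  set.seed(53)
  X <- matrix(rnorm(60 * 2), 60, 2)
  beta <- c(1, 3, -2)
  y <- drop(cbind(1, X) %*% beta) + rnorm(60, sd = 0.3)
  y[7] <- y[7] + 100
  rob <- unname(fit_robust_linear(X, y)$state$coefficients)
  ols <- unname(coef(lm(y ~ X)))
  expect_lt(sum(abs(rob - beta)), sum(abs(ols - beta)))
})

test_that("stepwise selection finds the predictive feature", {
  hits <- 0
  for (seed in 1:20) {
    set.seed(seed)
    X <- matrix(rnorm(200 * 10), 200, 10)
    y <- 2 * X[, 3] + rnorm(200)
    m <- fit_stepwise(X, y)
    if ("x3" %in% m$training_summary$selected_terms) hits <- hits + 1
  }
  expect_gte(hits, 18)
})

test_that("stepwise forward selection rarely admits pure noise", {
  empty <- 0
  for (seed in 1:100) {
    set.seed(seed)
    X <- matrix(rnorm(100 * 9), 100, 9)
    y <- rnorm(100)
    m <- fit_stepwise(X, y, direction = "forward")
    if (length(m$training_summary$selected_terms) == 0) empty <- empty + 1
  }
  expect_gt(empty, 50)
})

test_that("stepwise honors the step bound and threshold ordering", {
  set.seed(54)
  X <- matrix(rnorm(100 * 4), 100, 4)
  y <- X[, 1] + rnorm(100)
  m0 <- fit_stepwise(X, y, max_steps = 0)
  expect_equal(sort(m0$training_summary$selected_terms),
               sort(paste0("x", 1:4)))   # initial linear model untouched
  expect_equal(m0$training_summary$iterations, 0)
  expect_error(fit_stepwise(X, y, p_enter = 0.2, p_remove = 0.1),
               class = "chlorospec_config_error")
})

test_that("stepwise can build interaction terms when they drive the response", {
  set.seed(55)
  X <- matrix(rnorm(300 * 3), 300, 3)
  y <- X[, 1] + X[, 2] + 3 * X[, 1] * X[, 2] + rnorm(300, sd = 0.5)
  m <- fit_stepwise(X, y)
  expect_true("x1:x2" %in% m$training_summary$selected_terms)
  pred <- predict(m, X)
  expect_gt(cor(pred, y)^2, 0.9)
})

test_that("kernel functions match hand values and are positive definite", {
  expect_equal(kernel_gaussian(c(1, 2), c(1, 2), 0.5), 1)
  # distance sigma * sqrt(2) gives exp(-1)
  expect_equal(kernel_gaussian(c(0, 0), c(1, 1), 1), exp(-1))
  expect_error(kernel_gaussian(1:2, 1:3, 1), class = "chlorospec_input_error")
  expect_error(kernel_gaussian(1, 1, 0), class = "chlorospec_domain_error")

  expect_equal(kernel_matern52(0, sigma = 2.5), 2.5)
  expect_equal(kernel_matern52(1, 1, 1),
               (1 + sqrt(5) + 5 / 3) * exp(-sqrt(5)), tolerance = 1e-12)
  expect_equal(kernel_matern52(1, 1, 1), 0.5240, tolerance = 1e-4)
  expect_lt(kernel_matern52(10, 1, 1), 1e-6)
  r <- seq(0, 5, 0.1)
  expect_true(all(diff(kernel_matern52(r, 1.3, 0.7)) < 0))
  expect_error(kernel_matern52(-1), class = "chlorospec_domain_error")

  set.seed(56)
  P <- matrix(rnorm(20 * 3), 20, 3)
  G1 <- outer(1:20, 1:20, Vectorize(function(i, j)
    kernel_gaussian(P[i, ], P[j, ], 0.8)))
  D <- as.matrix(dist(P))
  G2 <- kernel_matern52(D, 1.2, 0.9)
  for (G in list(G1, G2)) {
    ev <- eigen((G + t(G)) / 2, symmetric = TRUE, only.values = TRUE)$values
    expect_gte(min(ev), -1e-10)
  }
})

test_that("quadratic-kernel SVR fits a noise-free quadratic target", {
  set.seed(57)
  X <- matrix(runif(150 * 2, -2, 2), 150, 2)
  y <- 3 + X[, 1]^2 - 2 * X[, 1] * X[, 2] + X[, 2]
  m <- fit_svr(X, y, kernel = "quadratic")
  r2 <- 1 - sum((y - predict(m, X))^2) / sum((y - mean(y))^2)
  expect_gt(r2, 0.99)
})

test_that("fine-Gaussian SVR stores its kernel scale and honors a wide tube", {
  set.seed(58)
  X <- matrix(rnorm(60 * 2), 60, 2)
  y <- rowSums(X) + rnorm(60, sd = 0.1)
  m <- fit_svr(X, y, kernel = "fine_gaussian")
  expect_equal(m$state$kernel_scale, 0.83)
  # epsilon wider than the response range: nearly constant prediction
  m2 <- fit_svr(X, y, kernel = "fine_gaussian",
                epsilon = diff(range(y)) * 2)
  expect_lt(sd(predict(m2, X)), 0.05 * sd(y))
  expect_error(fit_svr(X, c(y[-1], NA)), class = "chlorospec_input_error")
})

test_that("Matern 5/2 GPR interpolates, reverts and recovers", {
  set.seed(59)
  x <- matrix(runif(40, -3, 3))
  f <- sin(x[, 1])
  g0 <- fit_gpr(x, f, noise = 0, seed = 2)
  expect_lt(max(abs(predict(g0, x) - f)), 1e-6)
  # far from the data the posterior mean reverts to the constant basis
  far <- matrix(c(1e4, -1e4))
  reversion <- g0$state$y_mu + g0$state$y_sd * g0$state$cmean
  expect_equal(unname(predict(g0, far)), rep(reversion, 2), tolerance = 1e-8)

  xs <- matrix(runif(80, -3, 3))
  ys <- sin(xs[, 1]) + rnorm(80, sd = 0.1)
  g <- fit_gpr(xs, ys, seed = 3)
  grid <- matrix(seq(-3, 3, length.out = 150))
  expect_lt(sqrt(mean((predict(g, grid) - sin(grid[, 1]))^2)), 0.2)
  # optimization does not worsen the marginal likelihood
  expect_lte(g$training_summary$nll, g$training_summary$init_nll + 1e-8)
  # predictive uncertainty grows away from the data
  ps <- predict(g, rbind(0, 50), se = TRUE)
  expect_gt(ps$sd[2], ps$sd[1])
})

test_that("the trilayer network trains deterministically to capacity", {
  set.seed(60)
  X <- matrix(rnorm(500 * 4), 500, 4)
  y <- drop(X %*% c(1, -2, 0.5, 3)) + 5
  m <- fit_trilayer_nn(X, y, seed = 7)
  rmse <- sqrt(mean((predict(m, X) - y)^2))
  expect_lt(rmse, 0.01 * sd(y))
  m2 <- fit_trilayer_nn(X, y, seed = 7)
  expect_identical(m$state$theta, m2$state$theta)
  expect_identical(predict(m, X), predict(m2, X))
  m1 <- fit_trilayer_nn(X, y, iteration_limit = 1, seed = 7)
  expect_equal(m1$training_summary$iterations, 1)
  expect_false(m1$training_summary$converged)
  expect_error(fit_trilayer_nn(X[1:5, ], y[1:5]),
               class = "chlorospec_input_error")
})

test_that("prediction is a row-wise map with dimension checks", {
  set.seed(61)
  X <- matrix(rnorm(50 * 3), 50, 3)
  y <- rowSums(X) + rnorm(50, sd = 0.1)
  for (preset in c("robust_linear", "svm_quadratic", "gpr_matern52")) {
    m <- fit_model(preset, X, y, seed = 4)
    p <- predict(m, X)
    perm <- sample(50)
    expect_equal(predict(m, X[perm, , drop = FALSE]), p[perm],
                 tolerance = 1e-8, ignore_attr = TRUE)
    expect_length(predict(m, X[1, , drop = FALSE]), 1)
    expect_error(predict(m, X[, 1:2]), class = "chlorospec_input_error")
  }
  expect_error(fit_model("nope", X, y), class = "chlorospec_config_error")
})

test_that("standardization round-trips inputs", {
  set.seed(62)
  X <- matrix(rnorm(30 * 4, mean = 5, sd = 3), 30, 4)
  s <- chlorospec:::std_fit(X)
  Xs <- chlorospec:::std_apply(X, s)
  back <- sweep(sweep(Xs, 2, s$sd, "*"), 2, s$mean, "+")
  expect_equal(back, X, tolerance = 1e-12)
  expect_equal(unname(colMeans(Xs)), rep(0, 4), tolerance = 1e-12)
})
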