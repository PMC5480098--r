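test_that("the selected design is the intercept plus support columns", {
  set.seed(201)
  X <- matrix(rnorm(30 * 5), 30, 5)
  fit <- penalized_fit("lasso", "linear", 0.1, c(0, 0.4, 0, 0, -0.2))
  sel <- select_design(X, fit)
  expect_equal(sel$support, c(2L, 5L))
  expect_equal(dim(sel$XS), c(30L, 3L))
  expect_equal(sel$XS[, 1], rep(1, 30))
  expect_equal(unname(sel$XS[, 2:3]), X[, c(2, 5)])

  # empty support -> a single all-ones column
  sel0 <- select_design(X, penalized_fit("lasso", "linear", 0.1, rep(0, 5)))
  expect_equal(dim(sel0$XS), c(30L, 1L))

  # full support round-trips [1, X]
  selF <- select_design(X, penalized_fit("lasso", "linear", 0, rep(1, 5)))
  expect_equal(unname(selF$XS), unname(cbind(1, X)))

  # p_adapt >= n flags degeneracy
  Xs <- matrix(rnorm(3 * 5), 3, 5)
  expect_true(select_design(Xs, penalized_fit("x", "linear", 0,
                                              rep(1, 5)))$degenerate)
})

test_that("adaptive linear inference matches closed forms", {
  set.seed(202)
  y <- rnorm(40, 2)
  XS <- matrix(1, 40, 1, dimnames = list(NULL, "(Intercept)"))
  inf <- adaptive_inference_linear(list(XS = XS, support = integer(0)),
                                   y, mean(y))
  expect_equal(inf$sigma2_hat, var(y))            # sum sq / (n - 1)
  expect_equal(inf$covariance[1, 1], var(y) / 40)

  # orthonormal selected design: diagonal covariance sigma2 / n
  n <- 100
  Q <- orthonormal_design(n, 2, seed = 7)
  XSo <- cbind(1, Q)
  b <- c(0.5, 1, -1)
  yo <- drop(XSo %*% b) + rnorm(n)
  info <- adaptive_inference_linear(list(XS = XSo, support = 1:2), yo, b)
  expect_equal(info$covariance,
               diag(info$sigma2_hat / n, 3), tolerance = 1e-10)

  # random instance: covariance equals sigma2 * explicit inverse (QR oracle)
  set.seed(203)
  XSr <- cbind(1, matrix(rnorm(8 * 2), 8, 2))
  yr <- rnorm(8)
  br <- c(0.1, 0.2, -0.3)
  infr <- adaptive_inference_linear(list(XS = XSr, support = 1:2), yr, br)
  s2 <- sum((yr - XSr %*% br)^2) / (8 - 3)
  expect_equal(infr$covariance, s2 * qr.solve(crossprod(XSr)),
               tolerance = 1e-9)
})

test_that("oracle linear inference is the least-squares refit", {
  set.seed(204)
  XS <- cbind(1, matrix(rnorm(10 * 3), 10, 3))
  beta <- c(1, 0.5, -0.5, 2)
  y_exact <- drop(XS %*% beta)
  inf <- oracle_inference_linear(list(XS = XS, support = 1:3), y_exact)
  expect_equal(inf$estimates, beta, tolerance = 1e-9)
  expect_equal(inf$sigma2_hat, 0, tolerance = 1e-18)
  ci <- confidence_intervals(inf)
  expect_equal(ci$lower, ci$upper, tolerance = 1e-8)  # zero-width CIs

  y <- y_exact + rnorm(10)
  inf2 <- oracle_inference_linear(list(XS = XS, support = 1:3), y)
  expect_equal(inf2$estimates, unname(ols_oracle(XS, y)), tolerance = 1e-8)

  # stage-1 magnitudes do not matter: only the support enters
  X <- matrix(rnorm(50 * 4), 50, 4)
  yy <- rnorm(50)
  f1 <- penalized_fit("a", "linear", 0, c(0.9, 0, 0.1, 0))
  f2 <- penalized_fit("b", "linear", 5, c(-2, 0, 7, 0))
  o1 <- oracle_inference_linear(select_design(X, f1), yy)
  o2 <- oracle_inference_linear(select_design(X, f2), yy)
  expect_identical(o1$estimates, o2$estimates)
  expect_identical(o1$covariance, o2$covariance)
})

test_that("adaptive and oracle inference coincide for an unpenalized full fit", {
  set.seed(205)
  X <- matrix(rnorm(60 * 3), 60, 3)
  y <- drop(X %*% c(1, -1, 0.5)) + rnorm(60)
  sel <- select_design(X, penalized_fit("ols", "linear", 0, c(1, 1, 1)))
  ols <- ols_oracle(sel$XS, y)
  ad <- adaptive_inference_linear(sel, y, unname(ols))
  or <- oracle_inference_linear(sel, y)
  expect_equal(ad$sigma2_hat, or$sigma2_hat, tolerance = 1e-10)
  expect_equal(ad$covariance, or$covariance, tolerance = 1e-10)
  expect_equal(ad$estimates, or$estimates, tolerance = 1e-8)
})

test_that("adaptive logistic inference matches information-matrix oracles", {
  # all-zero coefficients: V = I/4, covariance = 4 (XS'XS)^-1
  set.seed(206)
  XS <- cbind(1, matrix(rnorm(50 * 2), 50, 2))
  y <- rbinom(50, 1, 0.5)
  inf <- adaptive_inference_logistic(list(XS = XS, support = 1:2), y,
                                     c(0, 0, 0))
  expect_equal(inf$covariance, 4 * qr.solve(crossprod(XS)),
               tolerance = 1e-9)

  # numeric Hessian of the log-likelihood at an arbitrary beta
  set.seed(207)
  XS2 <- cbind(1, matrix(rnorm(20 * 2), 20, 2))
  y2 <- rbinom(20, 1, 0.5)
  bb <- c(0.3, -0.6, 0.2)
  inf2 <- adaptive_inference_logistic(list(XS = XS2, support = 1:2), y2, bb)
  H <- logistic_hessian_oracle(XS2, bb)
  expect_equal(inf2$covariance, solve(H), tolerance = 1e-5)
})

test_that("single binary predictor at the MLE recovers the Woolf variance", {
  # 2x2 table: controls (x=0) a=30 b=20, cases (x=1) c=15 d=35
  x <- c(rep(0, 50), rep(1, 50))
  y <- c(rep(0, 30), rep(1, 20), rep(0, 15), rep(1, 35))
  XS <- cbind(1, x)
  mle <- irls_oracle(XS, y)
  inf <- adaptive_inference_logistic(list(XS = XS, support = 1L), y, mle)
  woolf <- 1 / 30 + 1 / 20 + 1 / 15 + 1 / 35
  expect_equal(inf$covariance[2, 2], woolf, tolerance = 1e-6)

  # oracle refit on the same data: slope = log odds ratio of the table
  orc <- oracle_inference_logistic(list(XS = XS, support = 1L), y)
  expect_equal(orc$estimates[2], log((35 / 15) / (20 / 30)),
               tolerance = 1e-6)
  expect_equal(orc$covariance[2, 2], woolf, tolerance = 1e-6)
})

test_that("oracle logistic refit agrees with an independent IRLS oracle", {
  set.seed(208)
  XS <- cbind(1, matrix(rnorm(30 * 2), 30, 2))
  y <- rbinom(30, 1, plogis(drop(XS %*% c(-0.5, 1, 0.5))))
  inf <- oracle_inference_logistic(list(XS = XS, support = 1:2), y)
  expect_false(inf$degenerate)
  expect_equal(inf$estimates, irls_oracle(XS, y), tolerance = 1e-6)

  # intercept-only closed form: logit of the case fraction
  XS0 <- matrix(1, 30, 1)
  inf0 <- oracle_inference_logistic(list(XS = XS0, support = integer(0)), y)
  expect_equal(inf0$estimates[1], qlogis(mean(y)), tolerance = 1e-8)

  # complete separation is flagged degenerate
  xs <- c(rnorm(15, -3), rnorm(15, 3))
  ys <- rep(c(0, 1), each = 15)
  infs <- oracle_inference_logistic(list(XS = cbind(1, xs), support = 1L), ys)
  expect_true(infs$degenerate)
})

test_that("confidence intervals follow the normal quantile and nest by level", {
  inf <- postselsim:::new_inference("oracle", "linear", integer(0), 0,
                                    matrix(1, 1, 1))
  ci <- confidence_intervals(inf, 0.95)
  expect_equal(ci$lower, -1.959964, tolerance = 1e-6)
  expect_equal(ci$upper, 1.959964, tolerance = 1e-6)

  ci50 <- confidence_intervals(inf, 0.5)
  expect_gt(ci50$lower, ci$lower)
  expect_lt(ci50$upper, ci$upper)

  # zero variance -> degenerate interval at the point estimate
  inf0 <- postselsim:::new_inference("oracle", "linear", integer(0), 0.7,
                                     matrix(0, 1, 1))
  ci0 <- confidence_intervals(inf0)
  expect_equal(ci0$lower, 0.7)
  expect_equal(ci0$upper, 0.7)
})

test_that("covariances are symmetric positive semi-definite across replicates", {
  m <- true_model("linear", p = 12, p_star = 4, magnitude = 0.5)
  for (r in 1:20) {
    d <- simulate_linear(m, NULL, 80, seed = 400 + r)
    fit <- fit_lasso(d$X, d$y, "linear",
                     tuning_grid(nlambda = 20, fold_seed = r))
    sel <- select_design(d$X, fit)
    or <- oracle_inference_linear(sel, d$y)
    if (or$degenerate) next
    expect_true(isSymmetric(or$covariance, tol = 1e-10))
    ev <- eigen(or$covariance, symmetric = TRUE, only.values = TRUE)$values
    expect_gte(min(ev), -1e-12)
  }
})
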