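test_that("axis-aligned separation and degenerate (no-signal) fits", {
  set.seed(1)
  n <- 1000
  tab <- data.frame(class = rep(c("a", "b"), each = n),
                    x1 = rnorm(2 * n) + rep(c(0, 10), each = n),
                    x2 = rnorm(2 * n))
  m <- fit_dfa(tab, "class", c("x1", "x2"))
  w <- m$coef[, 1] / sqrt(sum(m$coef[, 1]^2))
  expect_gt(abs(w[1]), 0.99)          # first discriminant axis ~ (1, 0)
  expect_lt(abs(w[2]), 0.1)
  tab$x1 <- rnorm(2 * n)              # equal class means: no signal
  m0 <- fit_dfa(tab, "class", c("x1", "x2"))
  expect_lt(max(abs(m0$eigenvalues)), 0.2)
  tab$x2 <- tab$x1                    # collinear: singular covariance
  expect_error(fit_dfa(tab, "class", c("x1", "x2")), "singular")
})

test_that("two-class coefficients are parallel to the Fisher closed form", {
  set.seed(7)
  for (rep_i in 1:5) {
    n <- 30; p <- 4
    A <- matrix(rnorm(p * p), p)
    Sigma <- crossprod(A) + diag(p)
    X <- matrix(rnorm(2 * n * p), ncol = p) %*% chol(Sigma)
    X[seq_len(n), ] <- X[seq_len(n), ] + rnorm(p)
    tab <- data.frame(class = rep(c("a", "b"), each = n), X)
    names(tab)[-1] <- paste0("x", 1:p)
    m <- fit_dfa(tab, "class", paste0("x", 1:p))
    # oracle: w = S_pooled^-1 (mu1 - mu2)
    mu <- m$means
    w_oracle <- solve(m$pooled_cov, mu[1, ] - mu[2, ])
    cos_angle <- abs(sum(m$coef[, 1] * w_oracle) /
                       sqrt(sum(m$coef[, 1]^2) * sum(w_oracle^2)))
    expect_gt(cos_angle, 1 - 1e-6)
  }
})

test_that("classification: class means, tie-break, Mahalanobis oracle", {
  set.seed(2)
  tab <- data.frame(class = rep(c("a", "b", "c"), each = 10),
                    x1 = rnorm(30) + rep(c(0, 8, 16), each = 10),
                    x2 = rnorm(30))
  m <- fit_dfa(tab, "class", c("x1", "x2"))
  # an observation at a class mean goes to that class
  for (k in 1:3)
    expect_equal(classify(m, data.frame(x1 = m$means[k, 1],
                                        x2 = m$means[k, 2])),
                 m$labels[k])
  expect_error(classify(m, data.frame(x1 = 1)), "lacks predictors")

  # documented tie-break: equidistant observation goes to the first label
  tie <- data.frame(class = rep(c("a", "b"), each = 4),
                    x1 = c(-1, -1, 1, 1, 3, 3, 5, 5) - 2,
                    x2 = c(-1, 1, -1, 1, -1, 1, -1, 1))
  mt <- fit_dfa(tie, "class", c("x1", "x2"))
  expect_equal(classify(mt, data.frame(x1 = 2 - 2, x2 = 0)), "a")

  # brute-force Mahalanobis-distance oracle on 200 random cases
  Sinv <- m$pooled_inv
  obs <- data.frame(x1 = rnorm(200, 8, 8), x2 = rnorm(200, 0, 3))
  got <- classify(m, obs)
  oracle <- apply(obs, 1, function(x) {
    d <- apply(m$means, 1, function(mu)
      mahalanobis(matrix(x, 1), mu, m$pooled_cov))
    m$labels[which.min(d)]
  })
  expect_identical(got, oracle)
})

test_that("LOOCV: perfect separation, refit oracle, permuted chance level", {
  set.seed(3)
  tab <- feature_fixture(K = 3, n_per = 8, p = 2, signal = 1, effect = 20)
  cv <- loocv(tab, "class", c("x1", "x2"))
  expect_equal(cv$cv_value, 100)
  expect_equal(sum(cv$confusion), cv$n)

  # explicit n-refit brute force on a 30-observation table
  tab <- feature_fixture(K = 3, n_per = 10, p = 3, signal = 1, effect = 1.2,
                         seed = 9)
  cv <- loocv(tab, "class", paste0("x", 1:3))
  oracle_pred <- vapply(seq_len(nrow(tab)), function(i) {
    m <- fit_dfa(tab[-i, ], "class", paste0("x", 1:3))
    classify(m, tab[i, ])
  }, character(1))
  expect_identical(cv$predicted, oracle_pred)
  expect_equal(cv$cv_value,
               100 * mean(oracle_pred == tab$class))

  # a class of size one cannot be left out
  expect_error(loocv(tab[-(1:9), ], "class", "x1"), "single observation")

  # permuted labels, 8 balanced classes: CV-value near 100/8 = 12.5%
  set.seed(4)
  cvs <- replicate(30, {
    t8 <- feature_fixture(K = 8, n_per = 5, p = 3, signal = 2, effect = 3,
                          seed = sample.int(1e6, 1))
    t8$class <- sample(t8$class)
    loocv(t8, "class", paste0("x", 1:3))$cv_value
  })
  expect_gt(mean(cvs), 12.5 - 3)
  expect_lt(mean(cvs), 12.5 + 3)
})

test_that("predictions are invariant under affine predictor transformations", {
  tab <- feature_fixture(K = 3, n_per = 10, p = 3, signal = 2, effect = 1,
                         seed = 12)
  preds <- paste0("x", 1:3)
  cv1 <- loocv(tab, "class", preds)
  tab2 <- tab
  tab2$x1 <- 50 * tab2$x1 - 3
  tab2$x3 <- -0.02 * tab2$x3 + 11
  cv2 <- loocv(tab2, "class", preds)
  expect_identical(cv1$predicted, cv2$predicted)
})

test_that("stepwise selection finds signal, respects margins and constraints", {
  # one informative predictor among noise
  tab <- feature_fixture(K = 4, n_per = 8, p = 5, signal = 1, effect = 4,
                         seed = 21)
  sel <- stepwise_select(tab, "class", paste0("x", 1:5))
  expect_true("x1" %in% sel$selected)
  expect_lt(length(sel$selected), 4)   # fewer variables than classes

  # degenerate margin: no move can improve by 100 points
  sel1 <- stepwise_select(tab, "class", paste0("x", 1:5), improvement = 1)
  expect_length(sel1$selected, 1)

  # forced predictor is retained regardless of its contribution
  sel2 <- stepwise_select(tab, "class", paste0("x", 1:5), forced = "x5")
  expect_true("x5" %in% sel2$selected)

  # deterministic given table and predictor order
  sel3 <- stepwise_select(tab, "class", paste0("x", 1:5))
  expect_identical(sel$selected, sel3$selected)
  expect_identical(sel$trace, sel3$trace)
  expect_error(stepwise_select(tab, "class", character()), "empty")
})

test_that("model agrees with the reference LDA implementation", {
  skip_if_not_installed("MASS")
  tab <- feature_fixture(K = 3, n_per = 15, p = 4, signal = 2, effect = 1.5,
                         seed = 31)
  preds <- paste0("x", 1:4)
  m <- fit_dfa(tab, "class", preds)
  ref <- MASS::lda(tab[, preds], grouping = tab$class,
                   prior = rep(1 / 3, 3))
  got <- classify(m, tab[, preds])
  want <- as.character(predict(ref, tab[, preds])$class)
  expect_gt(mean(got == want), 0.97)
})
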