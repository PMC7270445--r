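test_that("fit_linear recovers exact fits and hand-computed slopes", {
  x <- 1:5
  fit <- fit_linear(2 * x + 1, cbind(x = x))
  expect_equal(fit$terms$beta, c(1, 2), tolerance = 1e-12)
  expect_equal(fit$rss, 0, tolerance = 1e-20)

  # 6-point dataset, frozen from the normal equations:
  # Sxy = 13.5, Sxx = 17.5 -> slope 27/35, intercept 1.8
  x <- 1:6
  y <- c(2, 4, 5, 4, 5, 7)
  fit <- fit_linear(y, cbind(x = x))
  expect_equal(fit$terms$beta[2], 27 / 35, tolerance = 1e-12)
  expect_equal(fit$terms$beta[1], 1.8, tolerance = 1e-12)
  orc <- oracle_ols(y, cbind(x = x))
  expect_equal(fit$terms$beta, unname(orc$beta), tolerance = 1e-12)
  expect_equal(fit$terms$se, unname(orc$se), tolerance = 1e-12)

  # permutation invariance
  perm <- sample(6)
  fit2 <- fit_linear(y[perm], cbind(x = x[perm]))
  expect_equal(fit2$terms, fit$terms, tolerance = 1e-12)
})

test_that("fit_linear matches the normal-equations oracle on random designs", {
  set.seed(42)
  for (i in 1:100) {
    n <- sample(10:50, 1)
    p <- sample(1:5, 1)
    X <- matrix(rnorm(n * p), n, p,
                dimnames = list(NULL, paste0("v", seq_len(p))))
    y <- rnorm(n, mean = X %*% rnorm(p))
    fit <- fit_linear(y, X)
    orc <- oracle_ols(y, X)
    expect_equal(fit$terms$beta, unname(orc$beta), tolerance = 1e-8)
    expect_equal(fit$terms$se, unname(orc$se), tolerance = 1e-8)
  }
})

test_that("fit_linear names collinear columns on rank deficiency", {
  x <- rnorm(20)
  X <- cbind(a = x, b = 2 * x)
  expect_error(fit_linear(rnorm(20), X), "collinear.*b")
})

test_that("fit_logistic reproduces 2x2 closed forms", {
  d <- table_to_data(10, 10, 5, 20)
  fit <- fit_logistic(d$y, cbind(x = d$x))
  orc <- oracle_2x2(10, 10, 5, 20)
  expect_equal(fit$terms$beta[2], log(4), tolerance = 1e-6)
  expect_equal(fit$terms$beta[2], orc$log_or, tolerance = 1e-6)
  expect_equal(fit$terms$se[2], orc$se, tolerance = 1e-6)

  # intercept-only: logit of the overall proportion
  fit <- fit_logistic(c(rep(1, 30), rep(0, 70)), NULL)
  expect_equal(fit$terms$beta[1], log(30 / 70), tolerance = 1e-8)

  # random 2x2 tables
  set.seed(9)
  for (i in 1:20) {
    cells <- sample(3:40, 4, replace = TRUE)
    d <- table_to_data(cells[1], cells[2], cells[3], cells[4])
    fit <- fit_logistic(d$y, cbind(x = d$x))
    orc <- oracle_2x2(cells[1], cells[2], cells[3], cells[4])
    expect_equal(fit$terms$beta[2], orc$log_or, tolerance = 1e-6)
    expect_equal(fit$terms$se[2], orc$se, tolerance = 1e-6)
  }
})

test_that("fit_logistic under a null covariate gives a near-zero slope", {
  set.seed(31)
  x <- rnorm(400)
  y <- rbinom(400, 1, 0.5)
  fit <- fit_logistic(y, cbind(x = x))
  row <- fit$terms[fit$terms$term == "x", ]
  expect_lt(abs(row$beta), 3 * row$se)
  expect_true(fit$converged)
})

test_that("fit_logistic flags complete separation", {
  x <- c(rnorm(20, -3), rnorm(20, 3))
  y <- rep(c(0, 1), each = 20)
  fit <- fit_logistic(y, cbind(x = x))
  expect_false(fit$converged)
})

test_that("one-vs-reference multinomial collapses and relabels consistently", {
  set.seed(12)
  x <- rnorm(300)
  y2 <- factor(ifelse(rbinom(300, 1, plogis(0.5 + x)) == 1, "b", "a"),
               levels = c("a", "b"))
  multi <- fit_multinomial(y2, cbind(x = x), reference = "a")
  single <- fit_logistic(as.integer(y2 == "b"), cbind(x = x))
  expect_equal(multi$b$terms, single$terms, tolerance = 1e-10)
  # swapping the reference flips the signs
  flipped <- fit_multinomial(y2, cbind(x = x), reference = "b")
  expect_equal(flipped$a$terms$beta, -multi$b$terms$beta, tolerance = 1e-6)
})

test_that("multinomial recovers generating log-odds in a 3-level simulation", {
  set.seed(99)
  n <- 5000
  x <- rnorm(n)
  # generating model: log odds(b vs a) = -0.3 + 0.8 x; (c vs a) = 0.2 - 0.5 x
  eb <- exp(-0.3 + 0.8 * x); ec <- exp(0.2 - 0.5 * x)
  pr <- cbind(1, eb, ec) / (1 + eb + ec)
  y <- factor(apply(pr, 1, function(p) sample(c("a", "b", "c"), 1, prob = p)),
              levels = c("a", "b", "c"))
  fits <- fit_multinomial(y, cbind(x = x), reference = "a")
  bx <- fits$b$terms[fits$b$terms$term == "x", ]
  cx <- fits$c$terms[fits$c$terms$term == "x", ]
  expect_lt(abs(bx$beta - 0.8), 3 * bx$se)
  expect_lt(abs(cx$beta - (-0.5)), 3 * cx$se)
})

test_that("interaction_fit returns the product term and rejects degenerate designs", {
  set.seed(4)
  n <- 500
  grs <- rbinom(n, 12, 0.3)
  expo <- rnorm(n, 20, 8)
  y <- 1 + 0.2 * grs - 0.05 * expo + 0.1 * grs * expo + rnorm(n)
  fit <- interaction_fit(y, grs, expo)
  expect_equal(fit$interaction$term, "grs:exposure")
  expect_lt(abs(fit$interaction$beta - 0.1), 3 * fit$interaction$se)
  expect_error(interaction_fit(y, grs, rep(5, n)), "collinear")
})

test_that("t tests, correlation and KS screen behave as documented", {
  g <- c(1.2, 3.4, 2.2, 5.0, 4.1)
  ht <- two_sample_t(g, g)
  expect_equal(ht$t, 0)
  expect_equal(ht$p, 1)
  expect_error(two_sample_t(rep(1, 5), rep(1, 5) + 1), "zero variance")
  expect_error(two_sample_t(1:2, 1:5), "at least 3")

  pt <- paired_t(g, g)
  expect_equal(pt$t, 0)
  expect_equal(pt$p, 1)

  expect_equal(pearson_cor(1:10, 1:10)$r, 1)
  # 10-point printed fixture against the covariance-ratio formula
  x <- c(3.1, 4.7, 5.2, 6.8, 7.7, 8.1, 9.4, 10.2, 11.6, 12.3)
  y <- c(2.0, 4.9, 4.4, 7.2, 6.9, 9.0, 8.3, 11.1, 10.4, 13.0)
  r_hand <- sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  expect_equal(pearson_cor(x, y)$r, r_hand, tolerance = 1e-12)

  ks <- ks_normality(rnorm(100, 5, 2))
  expect_true(ks$D >= 0 && ks$D <= 1)
  expect_error(ks_normality(1:4), "at least 5")
})

test_that("two-sample t rejects at the nominal rate under the null", {
  set.seed(2024)
  reps <- 500
  p <- replicate(reps, two_sample_t(rnorm(20), rnorm(20))$p)
  rate <- mean(p < 0.05)
  mc_se <- sqrt(0.05 * 0.95 / reps)
  expect_lt(abs(rate - 0.05), 2 * mc_se + 1e-12)
})

test_that("Bonferroni thresholds scale exactly as 1/m", {
  fam9 <- bonferroni(0.05, 9)
  expect_equal(fam9$threshold, 0.05 / 9)
  expect_equal(fam9$display, 0.006)
  fam18 <- bonferroni(0.05, 18)
  expect_equal(fam18$threshold, 0.05 / 18)
  expect_equal(fam18$display, 0.003)
  expect_equal(bonferroni(0.05, 1)$threshold, 0.05)
  for (m in c(2, 5, 10, 36)) {
    expect_equal(bonferroni(0.05, m)$threshold * m, 0.05, tolerance = 1e-15)
  }
  expect_error(bonferroni(0.05, 0), "positive")
})

test_that("sample-size formula matches the worked example and scaling laws", {
  # exact quotient 2*3.24^2*18.5^2/13.08^2 = 41.99987...; the commonly
  # quoted 41.96 reflects rounded intermediates
  r <- sample_size(1.96, 1.28, 18.5, 13.08)
  expect_equal(r$n, 2 * 3.24^2 * 18.5^2 / 13.08^2, tolerance = 1e-12)
  expect_lt(abs(r$n - 41.96), 0.05)
  expect_equal(r$n_ceiling, 42)
  expect_equal(sample_size(1, 1, 1, 2)$n, 2)
  expect_equal(sample_size(1.96, 1.28, 2 * 18.5, 13.08)$n, 4 * r$n)
  expect_equal(sample_size(1.96, 1.28, 18.5, -13.08)$n, r$n)
  expect_error(sample_size(1.96, 1.28, 18.5, 0), "non-zero")
})
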