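test_that("regression metrics match hand-computed values", {
  d <- tibble::tibble(y = c(0, 10), yhat = c(0, 10))
  m <- regression_metrics(d, y, yhat)
  expect_equal(unlist(m[c("mae", "rmse", "r2")]), c(mae = 0, rmse = 0, r2 = 1))
  d2 <- tibble::tibble(y = c(0, 10), yhat = c(1, 9))
  m2 <- regression_metrics(d2, y, yhat)
  expect_equal(m2$mae, 1)
  expect_equal(m2$rmse, 1)
  expect_equal(m2$r2, 0.96) # SSres = 2, SStot = 50
  # the null model that predicts the mean scores R^2 = 0
  d3 <- tibble::tibble(y = c(2, 4, 9), yhat = rep(5, 3))
  expect_equal(regression_metrics(d3, y, yhat)$r2, 0)
  # constant truth: R^2 undefined
  d4 <- tibble::tibble(y = c(5, 5), yhat = c(4, 6))
  expect_warning(m4 <- regression_metrics(d4, y, yhat), "undefined")
  expect_true(is.nan(m4$r2))
})

test_that("rmse is never below mae", {
  set.seed(41)
  for (i in 1:25) {
    n <- sample(2:30, 1)
    d <- tibble::tibble(y = rnorm(n, 50, 20), yhat = rnorm(n, 50, 20))
    m <- suppressWarnings(regression_metrics(d, y, yhat))
    expect_gte(m$rmse, m$mae)
  }
})

test_that("spearman correlation matches hand-ranked cases", {
  d <- tibble::tibble(y = c(1, 2, 3), yhat = c(0, 0, 0),
                      s1 = c(10, 20, 30), s2 = c(30, 20, 10),
                      s3 = c(3, 1, 2))
  expect_equal(spearman_error_uncertainty(d, y, yhat, s1)$spearman_rho, 1)
  expect_equal(spearman_error_uncertainty(d, y, yhat, s2)$spearman_rho, -1)
  # d = (-2, 1, 1): rho = 1 - 6*6/(3*8) = -0.5
  expect_equal(spearman_error_uncertainty(d, y, yhat, s3)$spearman_rho, -0.5)
  dc <- tibble::tibble(y = c(1, 1), yhat = c(0, 0), s = c(1, 2))
  expect_warning(r <- spearman_error_uncertainty(dc, y, yhat, s), "undefined")
  expect_true(is.na(r$spearman_rho))
})

test_that("spearman is invariant under strictly increasing transforms", {
  set.seed(42)
  d <- tibble::tibble(y = rnorm(30, 50, 10), yhat = rnorm(30, 50, 10),
                      s = rexp(30))
  base <- spearman_error_uncertainty(d, y, yhat, s)$spearman_rho
  d$s_exp <- exp(d$s)
  d$s_aff <- 3 * d$s + 17
  expect_equal(spearman_error_uncertainty(d, y, yhat, s_exp)$spearman_rho,
               base, tolerance = 1e-12)
  expect_equal(spearman_error_uncertainty(d, y, yhat, s_aff)$spearman_rho,
               base, tolerance = 1e-12)
})

test_that("selective metrics keep the lowest-uncertainty fraction", {
  d <- tibble::tibble(y = c(1, 2, 3, 4), yhat = rep(0, 4),
                      s = c(1, 2, 3, 4))
  sm <- selective_metrics(d, y, yhat, s, coverage = 0.5)
  expect_equal(sm$kept_n, 2)
  expect_equal(sm$mae, 1.5) # kept errors {1, 2}
  full <- selective_metrics(d, y, yhat, s, coverage = 1)
  ref <- regression_metrics(d, y, yhat)
  expect_equal(full$mae, ref$mae)
  expect_equal(full$rmse, ref$rmse)
  expect_error(selective_metrics(d, y, yhat, s, coverage = 0), "coverage")
  # ties broken by original row order
  dt <- tibble::tibble(y = c(5, 1, 9, 2), yhat = rep(0, 4), s = rep(1, 4))
  smt <- selective_metrics(dt, y, yhat, s, coverage = 0.5)
  expect_equal(smt$mae, mean(c(5, 1)))
})

test_that("keep counts are exact and sweeps partition the data", {
  set.seed(43)
  n <- 37
  d <- tibble::tibble(y = rnorm(n), yhat = rnorm(n), s = runif(n))
  for (cv in c(0.1, 0.3, 0.5, 0.77, 1)) {
    expect_equal(selective_metrics(d, y, yhat, s, cv)$kept_n,
                 ceiling(cv * n))
  }
  # the kept set at higher coverage contains the kept set at lower coverage
  k30 <- kept_indices(d$s, 0.3)
  k80 <- kept_indices(d$s, 0.8)
  expect_true(all(k30 %in% k80))
  expect_setequal(kept_indices(d$s, 1), seq_len(n))
})

test_that("oracle-ranked coverage curves are non-increasing", {
  set.seed(44)
  d <- tibble::tibble(y = rnorm(200, 50, 15), yhat = rnorm(200, 50, 15))
  d$s <- abs(d$y - d$yhat) # oracle score: the true error
  cc <- coverage_curve(d, y, yhat, s)
  expect_equal(nrow(cc), 8)
  expect_equal(cc$coverage, seq(1, 0.3, by = -0.1))
  expect_true(all(diff(cc$mae) <= 1e-12)) # coverage descends, so mae must
  expect_true(all(diff(cc$rmse) <= 1e-12))
  expect_equal(cc$mae[1], regression_metrics(d, y, yhat)$mae)
})

test_that("uninformative scores leave the curve approximately flat", {
  # with scores independent of errors the rejected subset is random, so the
  # expected MAE is constant across coverages; check over repeated draws
  set.seed(45)
  reps <- 30; n <- 400
  delta <- replicate(reps, {
    y <- rnorm(n, 50, 10)
    yhat <- y + rnorm(n, 0, 5)
    s <- runif(n)
    d <- tibble::tibble(y = y, yhat = yhat, s = s)
    cc <- coverage_curve(d, y, yhat, s, coverages = c(1, 0.5))
    cc$mae[2] - cc$mae[1]
  })
  expect_lt(abs(mean(delta)), 3 * sd(delta) / sqrt(reps) + 0.05)
})

test_that("a single-coverage curve equals the full metrics", {
  d <- tibble::tibble(y = c(0, 10, 20), yhat = c(1, 9, 22), s = c(3, 2, 1))
  cc <- coverage_curve(d, y, yhat, s, coverages = 1)
  m <- regression_metrics(d, y, yhat)
  expect_equal(cc$mae, m$mae)
  expect_equal(cc$rmse, m$rmse)
  expect_equal(nrow(cc), 1)
})
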