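test_that("standardization fits population moments and round-trips", {
  s <- standardize_yields(c(0, 100))
  expect_equal(s$stats$mean, 50)
  expect_equal(s$stats$sd, 50) # population convention
  expect_equal(s$values, c(-1, 1))
  applied <- standardize_yields(50, stats = s$stats)
  expect_equal(applied$values, 0)
  expect_error(standardize_yields(c(5, 5, 5)), "zero variance")
  expect_error(standardize_yields(7), ">= 2")
  back <- destandardize_moments(s$values, c(1, 1), s$stats)
  expect_equal(back$mean, c(0, 100), tolerance = 1e-9)
  expect_equal(back$var, c(2500, 2500))
})

test_that("the per-sample loss term matches its closed form", {
  expect_equal(nll_term(1, 1, 0), 0)
  expect_equal(nll_term(2, 0, log(4)), 1 + log(4))
  expect_equal(nll_term(1, 0, 1), exp(-1) + 1)
})

test_that("the loss term is the Gaussian log-density up to its constant", {
  # log N(y | mu, s2) = -log(2*pi)/2 - nll_term/2
  expect_equal(-0.5 * log(2 * pi), -0.9189385, tolerance = 1e-7)
  set.seed(21)
  for (i in 1:50) {
    y <- rnorm(1); mu <- rnorm(1); s2 <- exp(rnorm(1))
    expect_equal(-0.5 * log(2 * pi) - 0.5 * nll_term(y, mu, log(s2)),
                 dnorm(y, mu, sqrt(s2), log = TRUE), tolerance = 1e-10)
  }
})

test_that("the blended objective evaluates and interpolates correctly", {
  expect_equal(yield_objective(c(1, 3), c(0, 0), c(5, -2), lambda = 0), 5)
  expect_equal(yield_objective(0, 0, 0, lambda = 1), 0)
  expect_equal(yield_objective(2, 0, log(4), lambda = 0.1),
               0.9 * 4 + 0.1 * (1 + log(4)), tolerance = 1e-12)
  expect_error(yield_objective(numeric(0), numeric(0), numeric(0), 0.5),
               "empty")
  # linear in lambda: J(lambda) = (1 - lambda) A + lambda B
  set.seed(31)
  y <- rnorm(8); mu <- rnorm(8); lv <- rnorm(8)
  A <- mean((y - mu)^2)
  B <- mean(nll_term(y, mu, lv))
  for (lam in c(0, 0.25, 0.5, 1)) {
    expect_equal(yield_objective(y, mu, lv, lam), (1 - lam) * A + lam * B,
                 tolerance = 1e-12)
  }
})

test_that("training reduces the loss and is seed-reproducible", {
  d <- generate_reactions(synth_spec(n = 200, seed = 5))
  dims <- yieldnet_dims(node_dim = 8, graph_dim = 32, fnn_dim = 16,
                        edge_hidden = 6)
  fit1 <- yieldnet(d, lambda = 0, epochs = 25, batch_size = 64, dims = dims,
                   seed = 2)
  expect_lt(dplyr::last(fit1$history$mse), fit1$history$mse[1])
  fit2 <- yieldnet(d, lambda = 0, epochs = 25, batch_size = 64, dims = dims,
                   seed = 2)
  expect_equal(fit1$history, fit2$history, tolerance = 1e-12)
  expect_identical(fit1$params$w, fit2$params$w)
})

test_that("training refuses records without yields", {
  d <- generate_reactions(synth_spec(n = 20, seed = 5))
  d$yield[3] <- NA
  expect_error(yieldnet(d, epochs = 1), "yield")
})

test_that("reported history is the data loss, excluding the L2 penalty", {
  d <- generate_reactions(synth_spec(n = 40, seed = 6))
  dims <- yieldnet_dims(node_dim = 5, graph_dim = 8, fnn_dim = 6,
                        edge_hidden = 4, dropout = 0)
  # lr = 0 freezes the parameters at initialization, so epoch-1 MSE must
  # equal the data MSE of the initial model no matter how large l2 is
  fit <- yieldnet(d, lambda = 0, epochs = 1, batch_size = 40, dims = dims,
                  seed = 3, lr = c(0, 0, 0), l2 = 10)
  std <- standardize_yields(d$yield)
  cfg <- fit$feature_config
  mu <- vapply(seq_len(nrow(d)), function(i) {
    rec <- featurize_reaction(
      unlist(d[i, c("reactant_1", "reactant_2", "reactant_3")]),
      d$product[i], d$yield[i], cfg)
    reaction_forward(rec, fit$params)$mu
  }, numeric(1))
  expect_equal(fit$history$mse[1], mean((std$values - mu)^2),
               tolerance = 1e-10)
})

test_that("the learning-rate schedule decays over the last fifth of epochs", {
  lr <- c(1e-3, 1e-4, 1e-5)
  sched <- vapply(1:500, lr_for_epoch, numeric(1), epochs = 500, lr = lr)
  expect_equal(unname(table(sched)[as.character(sort(lr))]),
               c(50, 50, 400), ignore_attr = TRUE)
  expect_equal(sched[400], 1e-3)
  expect_equal(sched[401], 1e-4)
  expect_equal(sched[451], 1e-5)
})

test_that("tidy and glance expose the history and a one-row summary", {
  d <- generate_reactions(synth_spec(n = 30, seed = 7))
  dims <- yieldnet_dims(node_dim = 4, graph_dim = 6, fnn_dim = 4,
                        edge_hidden = 3)
  fit <- yieldnet(d, epochs = 2, batch_size = 30, dims = dims, seed = 1)
  td <- generics::tidy(fit)
  expect_equal(nrow(td), 2)
  expect_true(all(c("epoch", "mse", "nll", "objective", "lr") %in% names(td)))
  gl <- generics::glance(fit)
  expect_equal(nrow(gl), 1)
  expect_equal(gl$n_train, 30)
  expect_equal(gl$lambda, 0.1)
})
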