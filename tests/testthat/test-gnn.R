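test_that("node embedding is an affine map with the right shape", {
  cfg <- tiny_config()
  par <- tiny_params()
  g <- featurize_molecule("C", cfg)
  h <- embed_nodes(g, par)
  expect_equal(dim(h), c(1, par$dims$node_dim))
  # zero weights give zero states (linearity)
  par0 <- par
  par0$w$embed_W <- par0$w$embed_W * 0
  par0$w$embed_b <- par0$w$embed_b * 0
  expect_equal(embed_nodes(featurize_molecule("CCO", cfg), par0),
               matrix(0, 3, par$dims$node_dim))
  # identical feature rows give identical states
  g2 <- featurize_molecule("CC", cfg)
  h2 <- embed_nodes(g2, par)
  expect_equal(h2[1, ], h2[2, ])
})

test_that("message passing agrees with an independent brute-force oracle", {
  cfg <- tiny_config()
  for (seed in 1:3) {
    par <- tiny_params(seed = seed)
    for (s in c("C", "CC", "CCO", "C1CC1", "CC(C)O")) {
      g <- featurize_molecule(s, cfg)
      h0 <- embed_nodes(g, par)
      got <- message_passing(g, h0, par, steps = 3)
      want <- oracle_message_passing(g, par, steps = 3)
      expect_lt(rel_diff(got, want), 1e-6)
    }
  }
})

test_that("an isolated node receives the zero message at every step", {
  cfg <- tiny_config()
  par <- tiny_params()
  g <- featurize_molecule("C", cfg)
  h0 <- embed_nodes(g, par)
  # oracle with empty neighbourhood is just the GRU applied to (h, 0)
  got <- message_passing(g, h0, par, steps = 3)
  want <- oracle_message_passing(g, par, steps = 3)
  expect_lt(rel_diff(got, want), 1e-12)
  expect_equal(dim(got), dim(h0))
})

test_that("message passing is equivariant under node relabeling", {
  cfg <- tiny_config()
  par <- tiny_params(seed = 4)
  g <- featurize_molecule("CC(C)O", cfg)
  perm <- c(3, 1, 4, 2)
  gp <- permute_graph(g, perm)
  h <- message_passing(g, embed_nodes(g, par), par)
  hp <- message_passing(gp, embed_nodes(gp, par), par)
  expect_lt(rel_diff(hp, h[perm, , drop = FALSE]), 1e-10)
})

test_that("set2set readout handles single and identical states correctly", {
  par <- tiny_params()
  d <- par$dims$node_dim
  # single node: attention weight 1; the read half equals that state
  h1 <- matrix(rnorm(d), 1, d)
  out1 <- set2set_readout(h1, par)
  expect_equal(out1[(d + 1):(2 * d)], as.vector(h1))
  # identical states: read is the common state regardless of weights
  h3 <- matrix(rep(h1, each = 3), 3, d)
  out3 <- set2set_readout(h3, par)
  expect_equal(out3[(d + 1):(2 * d)], as.vector(h1))
  expect_error(set2set_readout(matrix(0, 0, d), par), "at least one")
})

test_that("set2set readout is invariant to node order", {
  par <- tiny_params(seed = 2)
  d <- par$dims$node_dim
  set.seed(11)
  for (i in 1:10) {
    n <- sample(2:6, 1)
    h <- matrix(rnorm(n * d), n, d)
    out <- set2set_readout(h, par)
    outp <- set2set_readout(h[sample(n), , drop = FALSE], par)
    expect_lt(rel_diff(out, outp), 1e-6)
  }
})

test_that("graph representations are isomorphism-invariant with fixed length", {
  cfg <- tiny_config()
  par <- tiny_params(seed = 5)
  g <- featurize_molecule("CCO", cfg)
  expect_length(graph_repr(g, par), par$dims$graph_dim)
  r1 <- graph_repr(featurize_molecule("CCO", cfg), par)
  r2 <- graph_repr(featurize_molecule("OCC", cfg), par)
  expect_lt(rel_diff(r1, r2), 1e-6)
  perm <- c(2, 3, 1)
  expect_lt(rel_diff(graph_repr(permute_graph(g, perm), par), r1), 1e-10)
})

test_that("reaction outputs are reactant-order invariant and deterministic", {
  cfg <- tiny_config()
  par <- tiny_params(seed = 6)
  r1 <- featurize_reaction(c("CCO", "c1ccccc1", "CN"), "CC", 50, cfg)
  r2 <- featurize_reaction(c("CN", "CCO", "c1ccccc1"), "CC", 50, cfg)
  f1 <- reaction_forward(r1, par)
  f2 <- reaction_forward(r2, par)
  expect_lt(abs(f1$mu - f2$mu), 1e-6)
  expect_lt(abs(f1$log_var - f2$log_var), 1e-6)
  expect_identical(reaction_forward(r1, par), reaction_forward(r1, par))
  expect_length(f1$mu, 1)
  expect_length(f1$log_var, 1)
  expect_true(f1$log_var >= -10 && f1$log_var <= 10)
})

test_that("dropout makes forward passes stochastic under different streams", {
  cfg <- tiny_config()
  par <- tiny_params(seed = 6, dropout = 0.5)
  rec <- featurize_reaction(c("CCO"), "CC", 50, cfg)
  set.seed(1); a <- reaction_forward(rec, par, dropout = TRUE)
  set.seed(2); b <- reaction_forward(rec, par, dropout = TRUE)
  expect_false(isTRUE(all.equal(a$mu, b$mu)))
})

test_that("duplicating a reactant changes the representation (sum, not mean)", {
  cfg <- tiny_config()
  par <- tiny_params(seed = 7)
  r1 <- featurize_reaction(c("CCO"), "CC", 50, cfg)
  r2 <- featurize_reaction(c("CCO", "CCO"), "CC", 50, cfg)
  f1 <- reaction_forward(r1, par)
  f2 <- reaction_forward(r2, par)
  expect_false(isTRUE(all.equal(f1$mu, f2$mu)))
})

test_that("log-variance is clamped to [-10, 10]", {
  cfg <- tiny_config()
  par <- tiny_params(seed = 8)
  # force an extreme pre-clamp output through the final bias
  par$w$fnn_b3[2] <- 1e3
  rec <- featurize_reaction("CCO", "CC", 50, cfg)
  expect_equal(reaction_forward(rec, par)$log_var, 10)
  par$w$fnn_b3[2] <- -1e3
  expect_equal(reaction_forward(rec, par)$log_var, -10)
})
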