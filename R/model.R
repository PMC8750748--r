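# Permutation-invariant reaction representation and (mu, log sigma^2) head.
#
# Each molecular graph is encoded by an MPNN: nodes are embedded linearly,
# then updated for a fixed number of message passing steps where the message
# to a node is the sum over neighbours of an edge-conditioned linear map
# (the "edge network") applied to the neighbour state, and the update is a
# GRU cell shared across steps. A set2set readout pools the node states into
# an order-invariant vector, which a fully-connected "sparsifying" layer maps
# to the graph representation r. The reaction representation concatenates the
# sum of reactant r's with the product r; a two-hidden-layer feed-forward
# head with dropout emits the predictive mean and log-variance.
#
# All weights are stored input x output, so a forward step is `X %*% W + b`.
# Backward passes are hand-derived and verified against finite differences
# in the test suite.

LOGVAR_CLAMP <- 10

#' Model dimensions for the yield network
#'
#' Defaults follow the reference configuration: node states of dimension 64,
#' graph representations of dimension 1024, two 512-unit hidden layers in the
#' feed-forward head, and 3 message passing / 3 set2set processing steps.
#' Reduced widths (e.g. `node_dim = 16`, `graph_dim = 256`, `fnn_dim = 128`)
#' make desk-scale experiments fast while preserving the architecture.
#'
#' @param node_dim Node state dimension `d`.
#' @param graph_dim Graph representation dimension.
#' @param fnn_dim Width of the two hidden layers of the feed-forward head.
#' @param edge_hidden Hidden width of the two-layer edge network perceptron.
#' @param message_steps Number of message passing steps (weights shared).
#' @param set2set_steps Number of set2set processing steps.
#' @param dropout Dropout rate applied to the two feed-forward hidden layers.
#' @return A list of class `yieldnet_dims`.
#' @export
yieldnet_dims <- function(node_dim = 64, graph_dim = 1024, fnn_dim = 512,
                          edge_hidden = 2 * node_dim, message_steps = 3,
                          set2set_steps = 3, dropout = 0.1) {
  stopifnot(node_dim >= 1, graph_dim >= 1, fnn_dim >= 1, edge_hidden >= 1,
            message_steps >= 1, set2set_steps >= 1,
            dropout >= 0, dropout < 1)
  structure(
    list(node_dim = as.integer(node_dim), graph_dim = as.integer(graph_dim),
         fnn_dim = as.integer(fnn_dim), edge_hidden = as.integer(edge_hidden),
         message_steps = as.integer(message_steps),
         set2set_steps = as.integer(set2set_steps), dropout = dropout),
    class = "yieldnet_dims"
  )
}

glorot <- function(nin, nout) {
  s <- sqrt(6 / (nin + nout))
  matrix(stats::runif(nin * nout, -s, s), nin, nout)
}

#' Initialize model parameters
#'
#' Glorot-uniform weights, zero biases (set2set forget-gate bias starts at 1).
#' The feature configuration is embedded so a parameter set is self-describing
#' (`p` and `q` recorded).
#'
#' @param config A [feature_config()] fixing `p` and `q`.
#' @param dims A [yieldnet_dims()].
#' @param seed Integer seed for the initialization draw.
#' @return An object of class `yieldnet_params`.
#' @export
init_yieldnet_params <- function(config, dims = yieldnet_dims(), seed = 1) {
  stopifnot(inherits(config, "feature_config"), inherits(dims, "yieldnet_dims"))
  p <- config$p; q <- config$q
  d <- dims$node_dim; G <- dims$graph_dim; Fd <- dims$fnn_dim
  EH <- dims$edge_hidden
  w <- with_seed(seed, {
    w <- list(
      embed_W = glorot(p, d), embed_b = numeric(d),
      edge_W1 = glorot(q, EH), edge_b1 = numeric(EH),
      edge_W2 = glorot(EH, d * d), edge_b2 = numeric(d * d),
      gru_Wr = glorot(d, d), gru_Ur = glorot(d, d), gru_br = numeric(d),
      gru_Wz = glorot(d, d), gru_Uz = glorot(d, d), gru_bz = numeric(d),
      gru_Wn = glorot(d, d), gru_Un = glorot(d, d),
      gru_bn_i = numeric(d), gru_bn_h = numeric(d),
      s2s_Wi = glorot(2 * d, d), s2s_Ui = glorot(d, d), s2s_bi = numeric(d),
      s2s_Wf = glorot(2 * d, d), s2s_Uf = glorot(d, d),
      s2s_bf = rep(1, d),
      s2s_Wo = glorot(2 * d, d), s2s_Uo = glorot(d, d), s2s_bo = numeric(d),
      s2s_Wg = glorot(2 * d, d), s2s_Ug = glorot(d, d), s2s_bg = numeric(d),
      proj_W = glorot(2 * d, G), proj_b = numeric(G),
      fnn_W1 = glorot(2 * G, Fd), fnn_b1 = numeric(Fd),
      fnn_W2 = glorot(Fd, Fd), fnn_b2 = numeric(Fd),
      fnn_W3 = glorot(Fd, 2), fnn_b3 = numeric(2)
    )
    w
  })
  structure(list(w = w, dims = dims, p = p, q = q, config = config),
            class = "yieldnet_params")
}

#' @export
print.yieldnet_params <- function(x, ...) {
  n_par <- sum(vapply(x$w, length, numeric(1)))
  cat(sprintf(
    "<yieldnet_params> p=%d q=%d d=%d graph=%d fnn=%d (%s parameters)\n",
    x$p, x$q, x$dims$node_dim, x$dims$graph_dim, x$dims$fnn_dim,
    format(n_par, big.mark = ",")))
  invisible(x)
}

sigmoid <- function(x) 1 / (1 + exp(-x))
relu <- function(x) pmax(x, 0)
add_rows <- function(X, b) X + matrix(b, nrow(X), length(b), byrow = TRUE)

# ---- node embedding ---------------------------------------------------------

#' Embed node features into initial node states
#'
#' A learned affine map from the `p`-dimensional atom feature vectors to the
#' `d`-dimensional node states that seed message passing.
#'
#' @param graph A `molecular_graph`.
#' @param params A `yieldnet_params`.
#' @return An `n x d` matrix, one state per heavy atom.
#' @export
embed_nodes <- function(graph, params) {
  stopifnot(inherits(graph, "molecular_graph"),
            inherits(params, "yieldnet_params"))
  if (ncol(graph$node_features) != params$p) {
    stopf("graph has p=%d node features but params expect p=%d",
          ncol(graph$node_features), params$p)
  }
  add_rows(graph$node_features %*% params$w$embed_W, params$w$embed_b)
}

# Edge network: maps each bond feature vector to a d x d message matrix.
edge_matrices <- function(graph, params) {
  d <- params$dims$node_dim
  E <- nrow(graph$edge_index)
  if (E == 0L) {
    return(list(A = list(), A1 = matrix(0, 0, params$dims$edge_hidden)))
  }
  if (ncol(graph$edge_features) != params$q) {
    stopf("graph has q=%d edge features but params expect q=%d",
          ncol(graph$edge_features), params$q)
  }
  Z1 <- add_rows(graph$edge_features %*% params$w$edge_W1, params$w$edge_b1)
  A1 <- relu(Z1)
  Aflat <- add_rows(A1 %*% params$w$edge_W2, params$w$edge_b2)
  A <- lapply(seq_len(E), function(e) matrix(Aflat[e, ], d, d))
  list(A = A, A1 = A1)
}

# One GRU update over all nodes (rows), given messages M and states H.
gru_forward <- function(M, H, w) {
  R <- sigmoid(add_rows(M %*% w$gru_Wr + H %*% w$gru_Ur, w$gru_br))
  Z <- sigmoid(add_rows(M %*% w$gru_Wz + H %*% w$gru_Uz, w$gru_bz))
  Hn_h <- add_rows(H %*% w$gru_Un, w$gru_bn_h)
  Nn <- tanh(add_rows(M %*% w$gru_Wn, w$gru_bn_i) + R * Hn_h)
  list(H = (1 - Z) * Nn + Z * H, R = R, Z = Z, Nn = Nn, Hn_h = Hn_h)
}

mp_run <- function(H0, edge_index, A, params, steps, keep_cache = FALSE) {
  n <- nrow(H0)
  d <- ncol(H0)
  H <- H0
  cache <- if (keep_cache) vector("list", steps) else NULL
  E <- nrow(edge_index)
  for (t in seq_len(steps)) {
    M <- matrix(0, n, d)
    if (E > 0L) {
      for (e in seq_len(E)) {
        j <- edge_index[e, 1]; k <- edge_index[e, 2]
        M[j, ] <- M[j, ] + as.vector(A[[e]] %*% H[k, ])
        M[k, ] <- M[k, ] + as.vector(A[[e]] %*% H[j, ])
      }
    }
    g <- gru_forward(M, H, params$w)
    if (keep_cache) {
      cache[[t]] <- list(Hin = H, M = M, R = g$R, Z = g$Z, Nn = g$Nn,
                         Hn_h = g$Hn_h)
    }
    H <- g$H
  }
  list(H = H, cache = cache)
}

#' Run message passing over a molecular graph
#'
#' For each step, every node receives the sum over its neighbours of an
#' edge-network matrix applied to the neighbour state, and updates its state
#' through a GRU cell. Edge-network and GRU weights are shared across steps.
#'
#' @param graph A `molecular_graph`.
#' @param node_states `n x d` matrix of initial states (from [embed_nodes()]).
#' @param params A `yieldnet_params`.
#' @param steps Number of message passing steps.
#' @return The updated `n x d` node state matrix.
#' @export
message_passing <- function(graph, node_states, params,
                            steps = params$dims$message_steps) {
  stopifnot(nrow(node_states) == graph$n,
            ncol(node_states) == params$dims$node_dim)
  em <- edge_matrices(graph, params)
  mp_run(node_states, graph$edge_index, em$A, params, steps)$H
}

# ---- set2set readout --------------------------------------------------------

s2s_run <- function(H, params, steps, keep_cache = FALSE) {
  w <- params$w
  d <- params$dims$node_dim
  n <- nrow(H)
  q_state <- matrix(0, 1, d)
  c_state <- matrix(0, 1, d)
  x <- matrix(0, 1, 2 * d)
  cache <- if (keep_cache) vector("list", steps) else NULL
  for (s in seq_len(steps)) {
    i <- sigmoid(x %*% w$s2s_Wi + q_state %*% w$s2s_Ui +
                   matrix(w$s2s_bi, 1, d))
    f <- sigmoid(x %*% w$s2s_Wf + q_state %*% w$s2s_Uf +
                   matrix(w$s2s_bf, 1, d))
    o <- sigmoid(x %*% w$s2s_Wo + q_state %*% w$s2s_Uo +
                   matrix(w$s2s_bo, 1, d))
    g <- tanh(x %*% w$s2s_Wg + q_state %*% w$s2s_Ug + matrix(w$s2s_bg, 1, d))
    c_new <- f * c_state + i * g
    tanh_c <- tanh(c_new)
    q_new <- o * tanh_c
    logits <- as.vector(H %*% t(q_new))
    a <- exp(logits - max(logits))
    a <- a / sum(a)
    read <- matrix(a, 1, n) %*% H
    if (keep_cache) {
      cache[[s]] <- list(x_in = x, q_in = q_state, c_in = c_state,
                         i = i, f = f, o = o, g = g, c = c_new,
                         tanh_c = tanh_c, qn = q_new, a = a)
    }
    x <- cbind(q_new, read)
    q_state <- q_new
    c_state <- c_new
  }
  list(x = x, cache = cache)
}

#' set2set readout over node states
#'
#' Recurrent attention pooling: an LSTM cell produces a query from the
#' previous step's output, attention weights are the softmax of query-state
#' dot products, and the attended read vector is concatenated with the query.
#' The result is invariant to the order of the node states.
#'
#' @param node_states `n x d` matrix (`n >= 1`).
#' @param params A `yieldnet_params`.
#' @param steps Number of processing steps.
#' @return A numeric vector of length `2 d`.
#' @export
set2set_readout <- function(node_states, params,
                            steps = params$dims$set2set_steps) {
  if (is.null(dim(node_states)) || nrow(node_states) < 1L) {
    stopf("set2set readout needs at least one node state")
  }
  stopifnot(ncol(node_states) == params$dims$node_dim)
  as.vector(s2s_run(node_states, params, steps)$x)
}

# ---- full molecule encoder --------------------------------------------------

mol_forward <- function(graph, params, keep_cache = FALSE) {
  w <- params$w
  X <- graph$node_features
  H0 <- add_rows(X %*% w$embed_W, w$embed_b)
  em <- edge_matrices(graph, params)
  mp <- mp_run(H0, graph$edge_index, em$A, params,
               params$dims$message_steps, keep_cache)
  s2s <- s2s_run(mp$H, params, params$dims$set2set_steps, keep_cache)
  Zp <- s2s$x %*% w$proj_W + matrix(w$proj_b, 1, params$dims$graph_dim)
  r <- relu(Zp)
  cache <- if (keep_cache) {
    list(graph = graph, H0 = H0, A = em$A, A1 = em$A1, mp = mp$cache,
         H_final = mp$H, s2s = s2s$cache, x_out = s2s$x, Zp = Zp)
  }
  list(r = r, cache = cache)
}

# Backward pass through one molecule encoder. `dr` is 1 x graph_dim; grads are
# accumulated into the environment `gr` (same names as params$w).
mol_backward <- function(dr, cache, params, gr) {
  w <- params$w
  d <- params$dims$node_dim
  graph <- cache$graph
  n <- graph$n
  E <- nrow(graph$edge_index)

  dZp <- dr * (cache$Zp > 0)
  gr$proj_W <- gr$proj_W + crossprod(cache$x_out, dZp)
  gr$proj_b <- gr$proj_b + as.vector(dZp)
  dx <- tcrossprod(dZp, w$proj_W)

  H <- cache$H_final
  dH <- matrix(0, n, d)
  dq_next <- matrix(0, 1, d)
  dc_next <- matrix(0, 1, d)
  for (s in rev(seq_len(params$dims$set2set_steps))) {
    st <- cache$s2s[[s]]
    dqn <- dx[, 1:d, drop = FALSE] + dq_next
    dread <- dx[, (d + 1):(2 * d), drop = FALSE]
    da <- as.vector(H %*% t(dread))
    dH <- dH + matrix(st$a, n, 1) %*% dread
    dlogits <- st$a * (da - sum(st$a * da))
    dH <- dH + matrix(dlogits, n, 1) %*% st$qn
    dqn <- dqn + matrix(dlogits, 1, n) %*% H
    do_ <- dqn * st$tanh_c
    dc <- dc_next + dqn * st$o * (1 - st$tanh_c^2)
    di <- dc * st$g
    df <- dc * st$c_in
    dg <- dc * st$i
    dc_next <- dc * st$f
    dpi <- di * st$i * (1 - st$i)
    dpf <- df * st$f * (1 - st$f)
    dpo <- do_ * st$o * (1 - st$o)
    dpg <- dg * (1 - st$g^2)
    gr$s2s_Wi <- gr$s2s_Wi + crossprod(st$x_in, dpi)
    gr$s2s_Wf <- gr$s2s_Wf + crossprod(st$x_in, dpf)
    gr$s2s_Wo <- gr$s2s_Wo + crossprod(st$x_in, dpo)
    gr$s2s_Wg <- gr$s2s_Wg + crossprod(st$x_in, dpg)
    gr$s2s_Ui <- gr$s2s_Ui + crossprod(st$q_in, dpi)
    gr$s2s_Uf <- gr$s2s_Uf + crossprod(st$q_in, dpf)
    gr$s2s_Uo <- gr$s2s_Uo + crossprod(st$q_in, dpo)
    gr$s2s_Ug <- gr$s2s_Ug + crossprod(st$q_in, dpg)
    gr$s2s_bi <- gr$s2s_bi + as.vector(dpi)
    gr$s2s_bf <- gr$s2s_bf + as.vector(dpf)
    gr$s2s_bo <- gr$s2s_bo + as.vector(dpo)
    gr$s2s_bg <- gr$s2s_bg + as.vector(dpg)
    dx <- tcrossprod(dpi, w$s2s_Wi) + tcrossprod(dpf, w$s2s_Wf) +
      tcrossprod(dpo, w$s2s_Wo) + tcrossprod(dpg, w$s2s_Wg)
    dq_next <- tcrossprod(dpi, w$s2s_Ui) + tcrossprod(dpf, w$s2s_Uf) +
      tcrossprod(dpo, w$s2s_Uo) + tcrossprod(dpg, w$s2s_Ug)
  }
  # x_0, q_0, c_0 are constants; remaining dx/dq_next/dc_next vanish there

  dHout <- dH
  dAflat <- if (E > 0L) matrix(0, E, d * d) else NULL
  for (t in rev(seq_len(params$dims$message_steps))) {
    st <- cache$mp[[t]]
    Hin <- st$Hin
    dZ <- dHout * (Hin - st$Nn)
    dNn <- dHout * (1 - st$Z)
    dHin <- dHout * st$Z
    dPreN <- dNn * (1 - st$Nn^2)
    gr$gru_Wn <- gr$gru_Wn + t(st$M) %*% dPreN
    gr$gru_bn_i <- gr$gru_bn_i + colSums(dPreN)
    dM <- tcrossprod(dPreN, w$gru_Wn)
    dHn_h <- dPreN * st$R
    gr$gru_Un <- gr$gru_Un + crossprod(Hin, dHn_h)
    gr$gru_bn_h <- gr$gru_bn_h + colSums(dHn_h)
    dHin <- dHin + tcrossprod(dHn_h, w$gru_Un)
    dR <- dPreN * st$Hn_h
    dPreR <- dR * st$R * (1 - st$R)
    gr$gru_Wr <- gr$gru_Wr + t(st$M) %*% dPreR
    gr$gru_Ur <- gr$gru_Ur + crossprod(Hin, dPreR)
    gr$gru_br <- gr$gru_br + colSums(dPreR)
    dM <- dM + tcrossprod(dPreR, w$gru_Wr)
    dHin <- dHin + tcrossprod(dPreR, w$gru_Ur)
    dPreZ <- dZ * st$Z * (1 - st$Z)
    gr$gru_Wz <- gr$gru_Wz + t(st$M) %*% dPreZ
    gr$gru_Uz <- gr$gru_Uz + crossprod(Hin, dPreZ)
    gr$gru_bz <- gr$gru_bz + colSums(dPreZ)
    dM <- dM + tcrossprod(dPreZ, w$gru_Wz)
    dHin <- dHin + tcrossprod(dPreZ, w$gru_Uz)
    if (E > 0L) {
      for (e in seq_len(E)) {
        j <- graph$edge_index[e, 1]; k <- graph$edge_index[e, 2]
        A <- cache$A[[e]]
        dAflat[e, ] <- dAflat[e, ] +
          as.vector(outer(dM[j, ], Hin[k, ]) + outer(dM[k, ], Hin[j, ]))
        dHin[k, ] <- dHin[k, ] + as.vector(matrix(dM[j, ], 1, d) %*% A)
        dHin[j, ] <- dHin[j, ] + as.vector(matrix(dM[k, ], 1, d) %*% A)
      }
    }
    dHout <- dHin
  }

  if (E > 0L) {
    gr$edge_W2 <- gr$edge_W2 + crossprod(cache$A1, dAflat)
    gr$edge_b2 <- gr$edge_b2 + colSums(dAflat)
    dA1 <- tcrossprod(dAflat, w$edge_W2)
    dZ1 <- dA1 * (cache$A1 > 0)
    gr$edge_W1 <- gr$edge_W1 + crossprod(graph$edge_features, dZ1)
    gr$edge_b1 <- gr$edge_b1 + colSums(dZ1)
  }
  gr$embed_W <- gr$embed_W + crossprod(graph$node_features, dHout)
  gr$embed_b <- gr$embed_b + colSums(dHout)
  invisible(NULL)
}

#' Graph representation vector
#'
#' Composes embedding, message passing, set2set readout and the sparsifying
#' fully-connected layer (ReLU) into the graph representation `r`. Invariant
#' to node relabeling, hence to the SMILES spelling of a molecule.
#'
#' @param graph A `molecular_graph`.
#' @param params A `yieldnet_params`.
#' @return Numeric vector of length `graph_dim`.
#' @export
graph_repr <- function(graph, params) {
  as.vector(mol_forward(graph, params)$r)
}

# ---- reaction head ----------------------------------------------------------

# Feed-forward head over a batch of reaction representations (rows of Hmat).
# Dropout masks are drawn from the current RNG stream when rate > 0.
fnn_forward <- function(Hmat, params, dropout_rate = 0,
                        keep_cache = FALSE) {
  w <- params$w
  B <- nrow(Hmat)
  Fd <- params$dims$fnn_dim
  Z1 <- add_rows(Hmat %*% w$fnn_W1, w$fnn_b1)
  A1 <- relu(Z1)
  D1 <- if (dropout_rate > 0) {
    matrix((stats::runif(B * Fd) >= dropout_rate) / (1 - dropout_rate), B, Fd)
  } else {
    NULL
  }
  A1d <- if (is.null(D1)) A1 else A1 * D1
  Z2 <- add_rows(A1d %*% w$fnn_W2, w$fnn_b2)
  A2 <- relu(Z2)
  D2 <- if (dropout_rate > 0) {
    matrix((stats::runif(B * Fd) >= dropout_rate) / (1 - dropout_rate), B, Fd)
  } else {
    NULL
  }
  A2d <- if (is.null(D2)) A2 else A2 * D2
  Out <- add_rows(A2d %*% w$fnn_W3, w$fnn_b3)
  mu <- Out[, 1]
  log_var_raw <- Out[, 2]
  log_var <- pmin(pmax(log_var_raw, -LOGVAR_CLAMP), LOGVAR_CLAMP)
  res <- list(mu = mu, log_var = log_var,
              clamp_ok = (log_var_raw > -LOGVAR_CLAMP) &
                (log_var_raw < LOGVAR_CLAMP))
  if (keep_cache) {
    res$cache <- list(Hmat = Hmat, A1 = A1, D1 = D1, A1d = A1d,
                      A2 = A2, D2 = D2, A2d = A2d)
  }
  res
}

# Backward through the head; dOut is B x 2 (d mu, d log_var already masked by
# the clamp). Returns dHmat; accumulates grads into `gr`.
fnn_backward <- function(dOut, cache, params, gr) {
  w <- params$w
  gr$fnn_W3 <- gr$fnn_W3 + crossprod(cache$A2d, dOut)
  gr$fnn_b3 <- gr$fnn_b3 + colSums(dOut)
  dA2d <- tcrossprod(dOut, w$fnn_W3)
  dA2 <- if (is.null(cache$D2)) dA2d else dA2d * cache$D2
  dZ2 <- dA2 * (cache$A2 > 0)
  gr$fnn_W2 <- gr$fnn_W2 + crossprod(cache$A1d, dZ2)
  gr$fnn_b2 <- gr$fnn_b2 + colSums(dZ2)
  dA1d <- tcrossprod(dZ2, w$fnn_W2)
  dA1 <- if (is.null(cache$D1)) dA1d else dA1d * cache$D1
  dZ1 <- dA1 * (cache$A1 > 0)
  gr$fnn_W1 <- gr$fnn_W1 + crossprod(cache$Hmat, dZ1)
  gr$fnn_b1 <- gr$fnn_b1 + colSums(dZ1)
  tcrossprod(dZ1, w$fnn_W1)
}

#' Stochastic forward pass for one reaction
#'
#' Computes the reaction representation `h = [sum_l r^(R,l), r^(P)]` (sum over
#' reactant graph representations concatenated with the product's) and the
#' feed-forward head output `(mu, log sigma^2)` in standardized-yield units.
#' With `dropout = TRUE`, hidden units of the two head layers are dropped
#' independently at the configured rate using R's current RNG stream (seed it
#' for reproducibility); otherwise the pass is deterministic. The output is
#' invariant to permutations of the reactant list and to atom relabeling.
#'
#' @param record A `reaction_record`.
#' @param params A `yieldnet_params`.
#' @param dropout Whether to apply dropout to the head's hidden layers.
#' @return A list with `mu` and `log_var` (clamped to `[-10, 10]`).
#' @export
reaction_forward <- function(record, params, dropout = FALSE) {
  stopifnot(inherits(record, "reaction_record"))
  G <- params$dims$graph_dim
  r_sum <- numeric(G)
  for (g in record$reactants) r_sum <- r_sum + graph_repr(g, params)
  h <- matrix(c(r_sum, graph_repr(record$product, params)), 1, 2 * G)
  out <- fnn_forward(h, params,
                     dropout_rate = if (dropout) params$dims$dropout else 0)
  list(mu = unname(out$mu), log_var = unname(out$log_var))
}

zero_grads <- function(params) {
  gr <- new.env(parent = emptyenv())
  for (nm in names(params$w)) assign(nm, params$w[[nm]] * 0, envir = gr)
  gr
}
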