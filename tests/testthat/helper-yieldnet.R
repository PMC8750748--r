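# Shared fixtures and independent oracles, built in code at test time.

tiny_config <- function() {
  feature_config(smiles = c("C", "CC", "CCO", "CCN", "c1ccccc1", "C1CC1",
                            "CC(C)O", "CC(=O)O"))
}

tiny_dims <- function(dropout = 0) {
  yieldnet_dims(node_dim = 5, graph_dim = 7, fnn_dim = 6, edge_hidden = 4,
                dropout = dropout)
}

tiny_params <- function(seed = 1, dropout = 0, cfg = tiny_config()) {
  init_yieldnet_params(cfg, tiny_dims(dropout = dropout), seed = seed)
}

# Reduced-width configuration for desk-scale training experiments.
study_dims <- function() {
  yieldnet_dims(node_dim = 16, graph_dim = 256, fnn_dim = 128,
                edge_hidden = 32)
}

# Independent brute-force oracle for message passing: per-node loops and
# explicitly written edge-network / GRU gate equations, no shared code with
# the package's batched implementation.
oracle_message_passing <- function(graph, params, steps) {
  w <- params$w
  d <- params$dims$node_dim
  n <- graph$n
  E <- nrow(graph$edge_index)
  sig <- function(x) 1 / (1 + exp(-x))

  # initial states, one node at a time
  h <- vector("list", n)
  for (v in seq_len(n)) {
    h[[v]] <- as.vector(graph$node_features[v, ] %*% w$embed_W) + w$embed_b
  }
  # edge matrices, one bond at a time
  A <- vector("list", E)
  if (E > 0) {
    for (e in seq_len(E)) {
      hid <- as.vector(graph$edge_features[e, ] %*% w$edge_W1) + w$edge_b1
      hid <- ifelse(hid > 0, hid, 0)
      A[[e]] <- matrix(as.vector(hid %*% w$edge_W2) + w$edge_b2, d, d)
    }
  }
  for (step in seq_len(steps)) {
    m <- lapply(seq_len(n), function(v) numeric(d))
    if (E > 0) {
      for (e in seq_len(E)) {
        j <- graph$edge_index[e, 1]; k <- graph$edge_index[e, 2]
        m[[j]] <- m[[j]] + as.vector(A[[e]] %*% h[[k]])
        m[[k]] <- m[[k]] + as.vector(A[[e]] %*% h[[j]])
      }
    }
    h_new <- vector("list", n)
    for (v in seq_len(n)) {
      r <- sig(as.vector(m[[v]] %*% w$gru_Wr) + as.vector(h[[v]] %*% w$gru_Ur) +
                 w$gru_br)
      z <- sig(as.vector(m[[v]] %*% w$gru_Wz) + as.vector(h[[v]] %*% w$gru_Uz) +
                 w$gru_bz)
      nn <- tanh(as.vector(m[[v]] %*% w$gru_Wn) + w$gru_bn_i +
                   r * (as.vector(h[[v]] %*% w$gru_Un) + w$gru_bn_h))
      h_new[[v]] <- (1 - z) * nn + z * h[[v]]
    }
    h <- h_new
  }
  do.call(rbind, h)
}

# Build an isomorphic copy of a molecular graph under a node permutation.
permute_graph <- function(graph, perm) {
  inv <- order(perm) # inv[old] = new position
  ei <- graph$edge_index
  ei_new <- cbind(pmin(inv[ei[, 1]], inv[ei[, 2]]),
                  pmax(inv[ei[, 1]], inv[ei[, 2]]))
  colnames(ei_new) <- c("from", "to")
  structure(
    list(n = graph$n,
         node_features = graph$node_features[perm, , drop = FALSE],
         edge_index = ei_new,
         edge_features = graph$edge_features,
         smiles = graph$smiles),
    class = "molecular_graph"
  )
}

write_temp_csv <- function(lines) {
  path <- tempfile(fileext = ".csv")
  writeLines(lines, path)
  path
}

rel_diff <- function(a, b) {
  max(abs(a - b)) / max(1e-12, max(abs(a)), max(abs(b)))
}
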