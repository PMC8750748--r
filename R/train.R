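# Uncertainty-aware training.
#
# Yields are standardized to mean 0 / variance 1 over the training set; the
# objective blends a homoscedastic mean-squared-error term with the
# heteroscedastic Gaussian negative log-likelihood:
#
#   J(theta) = (1 - lambda) * mean_i (y_i - mu_i)^2
#            + lambda * mean_i [ (y_i - mu_i)^2 / sigma_i^2 + log sigma_i^2 ]
#
# The MSE term stabilizes training of the predictive mean; the NLL term lets
# the predicted variance absorb input-dependent (aleatoric) noise. Optimized
# with Adam under a piecewise-constant learning-rate decay and an L2 penalty
# on weight matrices (never biases); the penalty is excluded from reported
# loss history.

#' Standardize yields to mean 0, variance 1
#'
#' In fit mode (`stats = NULL`) the population mean and standard deviation
#' (1/N divisor) are computed from the supplied values, which must come from
#' the training split only. In apply mode the given statistics are reused.
#'
#' @param yields_percent Numeric vector of yields in percent.
#' @param stats Optional statistics from a previous fit-mode call.
#' @return A list with `values` (standardized yields) and `stats`
#'   (class `yield_stats`, fields `mean` and `sd` in percent).
#' @examples
#' standardize_yields(c(0, 100))
#' @export
standardize_yields <- function(yields_percent, stats = NULL) {
  y <- as.numeric(yields_percent)
  if (is.null(stats)) {
    if (length(y) < 2L) stopf("need >= 2 yields to fit standardization")
    m <- mean(y)
    s <- sqrt(mean((y - m)^2))
    if (s <= 0) stopf("yields have zero variance; cannot standardize")
    stats <- structure(list(mean = m, sd = s), class = "yield_stats")
  } else {
    stopifnot(inherits(stats, "yield_stats"))
  }
  list(values = (y - stats$mean) / stats$sd, stats = stats)
}

#' @export
print.yield_stats <- function(x, ...) {
  cat(sprintf("<yield_stats> mean=%.4f sd=%.4f (percent)\n", x$mean, x$sd))
  invisible(x)
}

#' Map standardized moments back to the percent scale
#'
#' Inverse of [standardize_yields()]: means transform affinely, variances by
#' the squared scale. Being a positive affine map, this preserves the ranking
#' of both predictions and uncertainty scores.
#'
#' @param mu_std Standardized mean(s).
#' @param var_std Standardized variance(s), non-negative.
#' @param stats A `yield_stats` object.
#' @return A list with `mean` (percent) and `var` (percent^2).
#' @export
destandardize_moments <- function(mu_std, var_std, stats) {
  stopifnot(inherits(stats, "yield_stats"))
  list(mean = mu_std * stats$sd + stats$mean, var = var_std * stats$sd^2)
}

#' Per-sample heteroscedastic Gaussian loss term
#'
#' `(y - mu)^2 * exp(-log_var) + log_var`: the Gaussian negative
#' log-likelihood with the additive constant `log(2 pi) / 2` and the factor
#' 1/2 dropped, as used in the blended training objective.
#'
#' @param y Observed value(s) (standardized units during training).
#' @param mu Predicted mean(s).
#' @param log_var Predicted log-variance(s).
#' @return Numeric vector of loss contributions.
#' @examples
#' nll_term(2, 0, log(4)) # 1 + log 4
#' @export
nll_term <- function(y, mu, log_var) {
  (y - mu)^2 * exp(-log_var) + log_var
}

#' Blended homoscedastic/heteroscedastic training objective
#'
#' `(1 - lambda) * mean squared error + lambda * mean nll_term`. At
#' `lambda = 0` this is exactly the mean squared error; at `lambda = 1` the
#' pure heteroscedastic Gaussian loss.
#'
#' @param y,mu,log_var Equal-length numeric vectors (a batch).
#' @param lambda Blend weight in `[0, 1]`.
#' @return A single number.
#' @examples
#' yield_objective(c(1, 3), c(0, 0), c(0, 0), lambda = 0) # mean(1, 9) = 5
#' @export
yield_objective <- function(y, mu, log_var, lambda) {
  if (length(y) == 0L) stopf("objective of an empty batch is undefined")
  stopifnot(length(mu) == length(y), length(log_var) == length(y))
  assert_scalar_number(lambda, "lambda", 0, 1)
  (1 - lambda) * mean((y - mu)^2) + lambda * mean(nll_term(y, mu, log_var))
}

# Piecewise-constant schedule: first 80% of epochs at lr[1], next 10% at
# lr[2], last 10% at lr[3] (at 500 epochs: 400/50/50).
lr_for_epoch <- function(epoch, epochs, lr) {
  b1 <- floor(0.8 * epochs)
  b2 <- floor(0.9 * epochs)
  if (epoch <= b1) lr[1] else if (epoch <= b2) lr[2] else lr[3]
}

adam_init <- function(params) {
  list(m = lapply(params$w, function(x) x * 0),
       v = lapply(params$w, function(x) x * 0),
       t = 0L)
}

adam_step <- function(params, gr, state, lr, l2,
                      beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  state$t <- state$t + 1L
  for (nm in names(params$w)) {
    g <- get(nm, envir = gr)
    if (l2 > 0 && grepl("_W", nm, fixed = TRUE)) {
      g <- g + l2 * params$w[[nm]]
    }
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * g
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * g^2
    mhat <- state$m[[nm]] / (1 - beta1^state$t)
    vhat <- state$v[[nm]] / (1 - beta2^state$t)
    params$w[[nm]] <- params$w[[nm]] - lr * mhat / (sqrt(vhat) + eps)
  }
  list(params = params, state = state)
}

# Pull reactant/product/yield columns out of a reaction tibble.
reaction_columns <- function(data, reactant_prefix, product_col, yield_col,
                             require_yield = TRUE) {
  stopifnot(is.data.frame(data))
  rcols <- grep(paste0("^", reactant_prefix), names(data), value = TRUE)
  if (length(rcols) < 1L) {
    stopf("no reactant columns found with prefix '%s'", reactant_prefix)
  }
  if (!product_col %in% names(data)) {
    stopf("product column '%s' not found", product_col)
  }
  has_yield <- yield_col %in% names(data)
  if (require_yield && !has_yield) {
    stopf("yield column '%s' not found", yield_col)
  }
  list(reactants = rcols, product = product_col,
       yield = if (has_yield) yield_col else NULL)
}

# Reactions as lists of molecule keys (SMILES strings), blanks dropped.
reaction_keys <- function(data, cols) {
  lapply(seq_len(nrow(data)), function(i) {
    rs <- as.character(unlist(data[i, cols$reactants]))
    rs <- rs[!is.na(rs) & nzchar(rs)]
    if (length(rs) < 1L) stopf("row %d has no reactant SMILES", i)
    list(reactants = rs, product = as.character(data[[cols$product]][i]))
  })
}

#' Fit the uncertainty-aware yield model
#'
#' Trains the graph-neural-network predictive distribution on a reaction
#' table: one row per reaction, reactant SMILES in columns sharing a common
#' name prefix (blank cells allowed, so the reactant count may vary by row),
#' one product SMILES column and one yield column in percent. Yields are
#' standardized over the training data; the blended objective
#' (see [yield_objective()]) is minimized with Adam under the configured
#' learning-rate schedule, dropout and L2 penalty. All randomness
#' (initialization, shuffling, dropout) derives from `seed`.
#'
#' @param data A data frame of reactions.
#' @param lambda Blend weight between the MSE and heteroscedastic NLL terms.
#' @param epochs,batch_size Optimization schedule (reference configuration:
#'   500 epochs, batches of 128; the last incomplete minibatch is kept).
#' @param lr Length-3 learning-rate levels: the first applies to the initial
#'   80% of epochs, the remaining two to the last 10% + 10%.
#' @param l2 L2 penalty factor on weight matrices (biases unpenalized).
#' @param dims A [yieldnet_dims()]; reduce widths for desk-scale runs.
#' @param feature_config Optional [feature_config()]; by default built from
#'   the elements observed in `data`.
#' @param seed Integer seed controlling all stochastic choices.
#' @param reactant_prefix,product_col,yield_col Column conventions.
#' @param verbose Print per-epoch losses.
#' @return An object of class `yieldnet` holding the fitted parameters,
#'   standardization statistics, feature configuration and a per-epoch
#'   `history` tibble (`epoch`, `mse`, `nll`, `objective`, `lr`; data terms
#'   only, excluding the L2 penalty).
#' @seealso [predict.yieldnet()], [tidy.yieldnet()], [glance.yieldnet()]
#' @export
yieldnet <- function(data, lambda = 0.1, epochs = 500, batch_size = 128,
                     lr = c(1e-3, 1e-4, 1e-5), l2 = 1e-5,
                     dims = yieldnet_dims(), feature_config = NULL, seed = 1,
                     reactant_prefix = "reactant", product_col = "product",
                     yield_col = "yield", verbose = FALSE) {
  assert_scalar_number(lambda, "lambda", 0, 1)
  stopifnot(epochs >= 1, batch_size >= 1, length(lr) == 3, l2 >= 0)
  cols <- reaction_columns(data, reactant_prefix, product_col, yield_col)
  y_raw <- data[[cols$yield]]
  if (anyNA(y_raw)) stopf("all training reactions must carry a yield")
  if (any(y_raw < 0 | y_raw > 100)) stopf("yields must lie in [0, 100]")
  n <- nrow(data)
  if (n < 2L) stopf("need at least two training reactions")

  reactions <- reaction_keys(data, cols)
  all_smiles <- unique(c(unlist(lapply(reactions, `[[`, "reactants")),
                         vapply(reactions, `[[`, character(1), "product")))
  if (is.null(feature_config)) {
    feature_config <- feature_config(smiles = all_smiles)
  }
  graphs <- featurize_unique(all_smiles, feature_config)

  std <- standardize_yields(y_raw)
  y <- std$values

  seeds <- derive_seeds(seed, 2)
  params <- init_yieldnet_params(feature_config, dims, seed = seeds[1])
  G <- dims$graph_dim

  history <- matrix(NA_real_, nrow = epochs, ncol = 4,
                    dimnames = list(NULL, c("mse", "nll", "objective", "lr")))
  opt <- adam_init(params)

  with_seed(seeds[2], {
    for (epoch in seq_len(epochs)) {
      lr_e <- lr_for_epoch(epoch, epochs, lr)
      idx <- sample.int(n)
      batches <- split(idx, ceiling(seq_along(idx) / batch_size))
      se_sum <- 0; nll_sum <- 0
      for (batch in batches) {
        B <- length(batch)
        keys <- unique(unlist(lapply(reactions[batch], function(r) {
          c(r$reactants, r$product)
        })))
        enc <- lapply(keys, function(k) {
          mol_forward(graphs[[k]], params, keep_cache = TRUE)
        })
        names(enc) <- keys
        Hmat <- matrix(0, B, 2 * G)
        for (bi in seq_len(B)) {
          r <- reactions[[batch[bi]]]
          acc <- numeric(G)
          for (k in r$reactants) acc <- acc + enc[[k]]$r
          Hmat[bi, 1:G] <- acc
          Hmat[bi, (G + 1):(2 * G)] <- enc[[r$product]]$r
        }
        out <- fnn_forward(Hmat, params, dropout_rate = dims$dropout,
                           keep_cache = TRUE)
        resid <- y[batch] - out$mu
        ev <- exp(-out$log_var)
        se <- resid^2
        nll <- se * ev + out$log_var
        se_sum <- se_sum + sum(se)
        nll_sum <- nll_sum + sum(nll)

        dmu <- (-2 * resid) * ((1 - lambda) + lambda * ev) / B
        ds <- lambda * (1 - se * ev) / B * out$clamp_ok
        gr <- zero_grads(params)
        dH <- fnn_backward(cbind(dmu, ds), out$cache, params, gr)
        dr_acc <- vector("list", length(keys))
        names(dr_acc) <- keys
        for (bi in seq_len(B)) {
          r <- reactions[[batch[bi]]]
          for (k in r$reactants) {
            dr_acc[[k]] <- (dr_acc[[k]] %||% 0) + dH[bi, 1:G]
          }
          dr_acc[[r$product]] <- (dr_acc[[r$product]] %||% 0) +
            dH[bi, (G + 1):(2 * G)]
        }
        for (k in keys) {
          if (!is.null(dr_acc[[k]])) {
            mol_backward(matrix(dr_acc[[k]], 1, G), enc[[k]]$cache, params, gr)
          }
        }
        upd <- adam_step(params, gr, opt, lr_e, l2)
        params <- upd$params
        opt <- upd$state
      }
      mse_e <- se_sum / n
      nll_e <- nll_sum / n
      history[epoch, ] <- c(mse_e, nll_e,
                            (1 - lambda) * mse_e + lambda * nll_e, lr_e)
      if (verbose) {
        message(sprintf("epoch %4d  mse %.4f  nll %.4f  lr %.1e",
                        epoch, mse_e, nll_e, lr_e))
      }
    }
  })

  structure(
    list(
      params = params,
      stats = std$stats,
      feature_config = feature_config,
      history = tibble::as_tibble(cbind(epoch = seq_len(epochs), history)),
      config = list(lambda = lambda, epochs = epochs,
                    batch_size = batch_size, lr = lr, l2 = l2,
                    dims = dims, seed = seed,
                    reactant_prefix = reactant_prefix,
                    product_col = product_col, yield_col = yield_col),
      n_train = n
    ),
    class = "yieldnet"
  )
}

#' @export
print.yieldnet <- function(x, ...) {
  cat(sprintf(
    "<yieldnet> trained on %d reactions (lambda=%g, %d epochs)\n",
    x$n_train, x$config$lambda, x$config$epochs))
  cat(sprintf("  final objective: %.4f (standardized units)\n",
              utils::tail(x$history$objective, 1)))
  print(x$params)
  invisible(x)
}
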