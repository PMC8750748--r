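# MC-dropout inference.
#
# T stochastic forward passes with dropout active approximate the Bayesian
# posterior predictive. The predictive mean is the average of the sampled
# means; the predictive variance decomposes into an aleatoric part (average
# of the sampled variances) and an epistemic part (population variance of the
# sampled means). Only the feed-forward head carries dropout, so the graph
# encoder runs once per molecule and the T passes re-use its output.

#' Decompose Monte-Carlo predictive samples into uncertainty components
#'
#' Given `T` sampled `(mu, sigma^2)` pairs from stochastic forward passes,
#' returns the aleatoric term `mean(var_samples)`, the epistemic term
#' `mean((mu_samples - mean(mu_samples))^2)` (population, 1/T divisor) and
#' their sum, computed as `aleatoric + epistemic` so the identity
#' `total = aleatoric + epistemic` holds exactly in floating point.
#'
#' @param mu_samples,var_samples Equal-length numeric vectors of sampled
#'   predictive means and variances.
#' @return A list with `aleatoric`, `epistemic` and `total`.
#' @examples
#' decompose_uncertainty(c(0, 2), c(1, 3)) # aleatoric 2, epistemic 1
#' @export
decompose_uncertainty <- function(mu_samples, var_samples) {
  if (length(mu_samples) != length(var_samples)) {
    stopf("mu_samples and var_samples must have equal length")
  }
  if (length(mu_samples) < 1L) stopf("need at least one sample")
  aleatoric <- mean(var_samples)
  mu_bar <- mean(mu_samples)
  epistemic <- mean((mu_samples - mu_bar)^2)
  list(aleatoric = aleatoric, epistemic = epistemic,
       total = aleatoric + epistemic)
}

# Shared MC-dropout engine over a matrix of reaction representations.
# Returns matrices (passes x n) of sampled means and variances, in
# standardized units.
mc_passes <- function(Hmat, params, passes, seed) {
  if (passes < 1L) stopf("number of forward passes must be >= 1")
  n <- nrow(Hmat)
  sub_seeds <- derive_seeds(seed, passes)
  mu_mat <- matrix(0, passes, n)
  var_mat <- matrix(0, passes, n)
  for (t in seq_len(passes)) {
    out <- with_seed(sub_seeds[t], {
      fnn_forward(Hmat, params, dropout_rate = params$dims$dropout)
    })
    mu_mat[t, ] <- out$mu
    var_mat[t, ] <- exp(out$log_var)
  }
  list(mu = mu_mat, var = var_mat)
}

reaction_h <- function(record, params) {
  G <- params$dims$graph_dim
  r_sum <- numeric(G)
  for (g in record$reactants) r_sum <- r_sum + graph_repr(g, params)
  matrix(c(r_sum, graph_repr(record$product, params)), 1, 2 * G)
}

#' MC-dropout prediction for a single reaction record
#'
#' Runs `passes` stochastic forward passes (dropout active in the head, each
#' pass on its own deterministic RNG substream derived from `seed`), then
#' decomposes the predictive variance. All quantities are reported on the
#' percent scale via the training standardization statistics: means map
#' affinely, variances by the squared scale.
#'
#' @param record A `reaction_record`.
#' @param params A trained `yieldnet_params`.
#' @param stats The `yield_stats` from training.
#' @param passes Number of stochastic forward passes `T` (default 30).
#' @param seed Integer seed for the dropout substreams.
#' @return An object of class `mc_predictive`: `mu_samples` (percent),
#'   `var_samples` (percent^2), `mean`, `aleatoric`, `epistemic`, `total`.
#' @export
mc_predict <- function(record, params, stats, passes = 30, seed = 1) {
  stopifnot(inherits(record, "reaction_record"),
            inherits(params, "yieldnet_params"),
            inherits(stats, "yield_stats"))
  H <- reaction_h(record, params)
  mp <- mc_passes(H, params, passes, seed)
  mu_pct <- as.vector(mp$mu) * stats$sd + stats$mean
  var_pct <- as.vector(mp$var) * stats$sd^2
  dec <- decompose_uncertainty(mu_pct, var_pct)
  structure(
    list(mu_samples = mu_pct, var_samples = var_pct,
         mean = mean(mu_pct), aleatoric = dec$aleatoric,
         epistemic = dec$epistemic, total = dec$total, passes = passes),
    class = "mc_predictive"
  )
}

#' @export
print.mc_predictive <- function(x, ...) {
  cat(sprintf(
    "<mc_predictive> T=%d: mean %.2f%%, total var %.3f (aleatoric %.3f + epistemic %.3f)\n",
    x$passes, x$mean, x$total, x$aleatoric, x$epistemic))
  invisible(x)
}

#' Predict yields with MC-dropout uncertainty for a reaction table
#'
#' Featurizes each unique molecule once, encodes it with the (deterministic)
#' graph encoder, then runs `passes` stochastic head passes per reaction and
#' decomposes the predictive variance. Identical `seed` values give
#' bit-identical predictions.
#'
#' @param object A fitted [yieldnet()] model.
#' @param newdata A data frame of reactions using the same column conventions
#'   as the training data (the yield column may be absent).
#' @param passes Number of MC-dropout forward passes `T` (default 30).
#' @param seed Integer seed for the dropout substreams.
#' @param score Which uncertainty component to expose as the ranking score
#'   in the `.uncertainty` column: total predictive variance (default), or
#'   the aleatoric/epistemic component alone.
#' @param ... Unused.
#' @return A tibble with one row per reaction: `.pred` (percent),
#'   `aleatoric_var`, `epistemic_var`, `total_var` (percent^2) and
#'   `.uncertainty` (the selected score).
#' @export
predict.yieldnet <- function(object, newdata, passes = 30, seed = 1,
                             score = c("total", "aleatoric", "epistemic"),
                             ...) {
  score <- match.arg(score)
  cfg <- object$config
  cols <- reaction_columns(newdata, cfg$reactant_prefix, cfg$product_col,
                           cfg$yield_col, require_yield = FALSE)
  reactions <- reaction_keys(newdata, cols)
  all_smiles <- unique(c(unlist(lapply(reactions, `[[`, "reactants")),
                         vapply(reactions, `[[`, character(1), "product")))
  graphs <- featurize_unique(all_smiles, object$feature_config)
  params <- object$params
  G <- params$dims$graph_dim
  reps <- lapply(graphs, function(g) as.vector(mol_forward(g, params)$r))
  n <- length(reactions)
  Hmat <- matrix(0, n, 2 * G)
  for (i in seq_len(n)) {
    r <- reactions[[i]]
    acc <- numeric(G)
    for (k in r$reactants) acc <- acc + reps[[k]]
    Hmat[i, 1:G] <- acc
    Hmat[i, (G + 1):(2 * G)] <- reps[[r$product]]
  }
  mp <- mc_passes(Hmat, params, passes, seed)
  stats <- object$stats
  mu_pct <- mp$mu * stats$sd + stats$mean       # passes x n
  var_pct <- mp$var * stats$sd^2
  mean_p <- colMeans(mu_pct)
  aleatoric <- colMeans(var_pct)
  epistemic <- colMeans(sweep(mu_pct, 2, mean_p)^2)
  total <- aleatoric + epistemic
  tibble::tibble(
    .pred = mean_p,
    aleatoric_var = aleatoric,
    epistemic_var = epistemic,
    total_var = total,
    .uncertainty = switch(score, total = total, aleatoric = aleatoric,
                          epistemic = epistemic)
  )
}
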