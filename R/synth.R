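# Synthetic combinatorial reaction datasets with known heteroscedastic noise.
#
# Real high-throughput yield benchmarks combine a few reusable component
# molecules (aryl cores, ligands, bases, additives) combinatorially, and the
# measurement noise differs between reaction subfamilies. The generator
# emulates exactly that statistical structure at toy scale: a deterministic
# base yield built from additive per-component effects plus one pairwise
# interaction, and Gaussian noise whose standard deviation depends on one
# designated component role. The generating truth is carried in `true_*`
# columns so tests can check parameter recovery; the CSV writer keeps those
# out of training files.

.toy_pool <- c(
  "C", "CC", "CCC", "CCCC", "CC(C)C", "CCCCC",
  "c1ccccc1", "Cc1ccccc1", "CCc1ccccc1", "Oc1ccccc1", "Nc1ccccc1",
  "Clc1ccccc1", "Brc1ccccc1", "Cc1ccc(C)cc1",
  "CO", "CCO", "CCCO", "CC(C)O", "OCCO",
  "CN", "CCN", "CCCN", "CC(C)N", "NCCN"
)

#' Built-in toy molecules
#'
#' The first `k` entries of a fixed list of small, chemically valid SMILES
#' (alkanes, substituted benzenes, alcohols, amines). Deterministic: the same
#' `k` always returns the same molecules.
#'
#' @param k Number of molecules (at most `length of the built-in list`).
#' @return Character vector of `k` distinct SMILES.
#' @export
toy_molecules <- function(k) {
  if (!is.numeric(k) || length(k) != 1L || k < 1) {
    stopf("`k` must be a positive integer")
  }
  if (k > length(.toy_pool)) {
    stopf("only %d built-in toy molecules available (asked for %d)",
          length(.toy_pool), k)
  }
  .toy_pool[seq_len(k)]
}

#' Specification for a synthetic reaction dataset
#'
#' Three reactant roles (core, ligand, base) drawn from disjoint slices of
#' the built-in molecule list, one product per core. The base yield of a
#' combination is 50 plus additive per-component effects plus a core-ligand
#' interaction, clipped to `[20, 80]` so that measurement noise rarely hits
#' the physical yield bounds. Noise standard deviation is attached to the
#' ligand role: the first half of the ligands gets `noise_sd[1]`, the second
#' half `noise_sd[2]`, giving two designed noise groups.
#'
#' @param n Number of reactions to generate.
#' @param n_core,n_ligand,n_base Pool sizes per role.
#' @param noise_sd Length-2 noise standard deviations (percent points) for
#'   the low- and high-noise ligand groups.
#' @param seed Integer seed fixing both the effect tables and the sampling.
#' @return An object of class `synth_spec`.
#' @export
synth_spec <- function(n = 2000, n_core = 8, n_ligand = 4, n_base = 3,
                       noise_sd = c(2, 12), seed = 42) {
  stopifnot(n >= 1, n_core >= 1, n_ligand >= 2, n_base >= 1,
            length(noise_sd) == 2, all(noise_sd >= 0))
  need <- 2 * n_core + n_ligand + n_base
  if (need > length(.toy_pool)) {
    stopf("role pools need %d molecules but only %d are built in", need,
          length(.toy_pool))
  }
  pool <- toy_molecules(need)
  cores <- pool[seq_len(n_core)]
  ligands <- pool[n_core + seq_len(n_ligand)]
  bases <- pool[n_core + n_ligand + seq_len(n_base)]
  products <- pool[n_core + n_ligand + n_base + seq_len(n_core)]
  seeds <- derive_seeds(seed, 2)
  effects <- with_seed(seeds[1], list(
    core = stats::runif(n_core, -15, 15),
    ligand = stats::runif(n_ligand, -8, 8),
    base = stats::runif(n_base, -5, 5),
    interaction = matrix(stats::runif(n_core * n_ligand, -5, 5),
                         n_core, n_ligand)
  ))
  lig_sd <- rep(noise_sd, c(ceiling(n_ligand / 2), floor(n_ligand / 2)))
  structure(
    list(n = as.integer(n), cores = cores, ligands = ligands, bases = bases,
         products = products, effects = effects, ligand_sd = lig_sd,
         noise_sd = noise_sd, seed = seed, sample_seed = seeds[2]),
    class = "synth_spec"
  )
}

#' @export
print.synth_spec <- function(x, ...) {
  cat(sprintf(
    "<synth_spec> %d reactions from %d cores x %d ligands x %d bases; noise sd {%s}\n",
    x$n, length(x$cores), length(x$ligands), length(x$bases),
    paste(x$noise_sd, collapse = ", ")))
  invisible(x)
}

# Deterministic base yield for a component combination, in [20, 80].
base_yield <- function(spec, core, ligand, base) {
  e <- spec$effects
  pmin(80, pmax(20, 50 + e$core[core] + e$ligand[ligand] + e$base[base] +
                  e$interaction[cbind(core, ligand)]))
}

#' Generate a synthetic reaction dataset
#'
#' Samples component combinations uniformly with the spec's seeded RNG and
#' draws `yield = clip(base_yield + N(0, sd_group), 0, 100)`. The returned
#' tibble uses the package's reaction CSV conventions (`reactant_1..3`,
#' `product`, `yield`) plus component annotations (`core`, `ligand`, `base`)
#' and hidden ground truth (`true_yield`, `true_sd`, `true_noise_group`)
#' that [write_reaction_csv()] keeps out of training files.
#'
#' @param spec A [synth_spec()].
#' @return A tibble with `spec$n` rows.
#' @export
generate_reactions <- function(spec) {
  stopifnot(inherits(spec, "synth_spec"))
  with_seed(spec$sample_seed, {
    core <- sample.int(length(spec$cores), spec$n, replace = TRUE)
    ligand <- sample.int(length(spec$ligands), spec$n, replace = TRUE)
    base <- sample.int(length(spec$bases), spec$n, replace = TRUE)
    mu <- base_yield(spec, core, ligand, base)
    sd_i <- spec$ligand_sd[ligand]
    y <- pmin(100, pmax(0, mu + stats::rnorm(spec$n, 0, sd_i)))
    tibble::tibble(
      reactant_1 = spec$cores[core],
      reactant_2 = spec$ligands[ligand],
      reactant_3 = spec$bases[base],
      product = spec$products[core],
      yield = y,
      core = core, ligand = ligand, base = base,
      true_yield = mu,
      true_sd = sd_i,
      true_noise_group = ifelse(sd_i == max(spec$ligand_sd), "high", "low")
    )
  })
}
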