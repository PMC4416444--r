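#' Gaussian fitness environments
#'
#' An environment is a point on the arbitrary `[0, 1]` niche axis plus the
#' variance of a Gaussian fitness kernel. Fitness of a species with optimum
#' `o` is `exp(-(o - value)^2 / (2 * variance))` -- an unnormalized kernel
#' with maximum 1 at the optimum. A small variance means strong selection.
#'
#' Two reference environments are provided: [blue_environment()] (value
#' 0.05, variance 0.175; weak selection) and [red_environment()] (value
#' 0.95, variance 0.0075; strong selection).
#'
#' @param value environment position in `[0, 1]`.
#' @param variance variance of the fitness kernel (> 0).
#' @return list of class `"fitness_env"`.
#' @export
fitness_env <- function(value, variance) {
  if (variance <= 0) stop("kernel variance must be positive")
  if (value < 0 || value > 1) stop("environment value must lie in [0, 1]")
  structure(list(value = value, variance = variance), class = "fitness_env")
}

#' @rdname fitness_env
#' @export
blue_environment <- function() fitness_env(0.05, 0.175)

#' @rdname fitness_env
#' @export
red_environment <- function() fitness_env(0.95, 0.0075)

#' Gaussian fitness of niche optima in an environment
#'
#' @param optimum numeric vector of niche optima.
#' @param env a [fitness_env()].
#' @return fitness values in `(0, 1]`.
#' @export
gaussian_fitness <- function(optimum, env) {
  stopifnot(inherits(env, "fitness_env"))
  exp(-(optimum - env$value)^2 / (2 * env$variance))
}

#' Assemble a local community from the regional pool
#'
#' Draws `n_species` species without replacement with probabilities
#' proportional to their fitness in `env`, optionally increased by an
#' additive dispersal term `dispersal_coef * (abundance in the source
#' community ^ dispersal_exponent)` that models mass effects from a focal
#' community. One individual seeds each drawn species and the remaining
#' individuals are drawn multinomially with the same (renormalized) modified
#' probabilities, so every community has exactly `n_species` species with
#' nonzero abundance and exactly `n_individuals` individuals.
#'
#' Uses (and advances) the current RNG stream unless `seed` is given.
#'
#' @param pool a [evolve_pool()] result.
#' @param env a [fitness_env()].
#' @param n_species community richness (default 100).
#' @param n_individuals community size (default 10000).
#' @param source optional named abundance vector of the dispersal source
#'   community (taxa absent from it contribute no dispersal).
#' @param dispersal_coef additive dispersal coefficient (default 0.05).
#' @param dispersal_exponent exponent on source abundance (default 1.1; a
#'   larger exponent means a higher effective dispersal rate).
#' @param seed optional integer seed.
#' @return named abundance vector over all extant pool species (zeros for
#'   absent species).
#' @export
assemble_community <- function(pool, env, n_species = 100,
                               n_individuals = 10000, source = NULL,
                               dispersal_coef = 0.05,
                               dispersal_exponent = 1.1, seed = NULL) {
  if (pool$richness < n_species)
    stop("regional pool has ", pool$richness, " species; need ", n_species)
  if (n_individuals < n_species)
    stop("community size must be at least its richness")
  w <- gaussian_fitness(pool$optima, env)
  if (!is.null(source)) {
    d <- numeric(length(w))
    names(d) <- names(w)
    common <- intersect(names(source)[source > 0], names(w))
    d[common] <- dispersal_coef * source[common]^dispersal_exponent
    w <- w + d
  }
  with_seed_(seed, {
    idx <- sample.int(length(w), n_species, prob = w)
    p <- w[idx] / sum(w[idx])
    out <- numeric(length(w))
    names(out) <- names(pool$optima)
    out[idx] <- 1 + as.numeric(stats::rmultinom(1L, n_individuals - n_species, p))
    out
  })
}

#' The seven-community validation scenario set
#'
#' Assembles the seven benchmark communities used to validate the inference
#' rules: communities 1-4 in the weak-selection blue environment and 5-7 in
#' the strong-selection red environment; communities 2, 3, and 5 receive
#' dispersal from community 1 (exponents 1.1, 0.8, and 1.1).
#'
#' @param pool a [evolve_pool()] result.
#' @param seed optional integer seed.
#' @inheritParams assemble_community
#' @return a [community_matrix()] with samples `C1`..`C7`.
#' @export
assemble_scenarios <- function(pool, seed = NULL, n_species = 100,
                               n_individuals = 10000) {
  blue <- blue_environment(); red <- red_environment()
  with_seed_(seed, {
    c1 <- assemble_community(pool, blue, n_species, n_individuals)
    m <- rbind(
      C1 = c1,
      C2 = assemble_community(pool, blue, n_species, n_individuals,
                              source = c1, dispersal_exponent = 1.1),
      C3 = assemble_community(pool, blue, n_species, n_individuals,
                              source = c1, dispersal_exponent = 0.8),
      C4 = assemble_community(pool, blue, n_species, n_individuals),
      C5 = assemble_community(pool, red, n_species, n_individuals,
                              source = c1, dispersal_exponent = 1.1),
      C6 = assemble_community(pool, red, n_species, n_individuals),
      C7 = assemble_community(pool, red, n_species, n_individuals))
    community_matrix(m)
  })
}
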