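#' Parameters of the regional-pool diversification model
#'
#' The regional pool evolves by asexual speciation and stochastic extinction
#' under a fixed total number of individuals. Population sizes are equal
#' across extant species (total / richness) and are re-imposed after each
#' step's events. Per time step, every species speciates with probability
#' `1 - exp(-speciation_coef * N)` (increasing in population size `N`), the
#' descendant's environmental optimum deviates from its ancestor's by a
#' Gaussian step (SD `mutation_sd`) reflected into `[0, 1]`, and every
#' species then goes extinct with probability `exp(-extinction_coef * N)`
#' (declining in `N`). Richness equilibrates where the two probabilities
#' balance; at the defaults (`speciation_coef = 1e-4`) the equilibrium is of
#' order 1e3 species.
#'
#' @param n_individuals total individuals summed over species (default 2e6).
#' @param n_steps number of time steps (default 250).
#' @param extinction_coef coefficient of the negative-exponential extinction
#'   probability (default 0.001).
#' @param mutation_sd SD of the Gaussian optimum mutation (default 0.15).
#' @param speciation_coef rate constant of the speciation probability
#'   (default 1e-4; calibrated so equilibrium richness falls near 1.1e3).
#' @param reflect reflect mutated optima at the `[0, 1]` boundary (default);
#'   `FALSE` clamps instead.
#' @return list of class `"pool_params"`.
#' @export
pool_params <- function(n_individuals = 2e6, n_steps = 250,
                        extinction_coef = 0.001, mutation_sd = 0.15,
                        speciation_coef = 1e-4, reflect = TRUE) {
  p <- list(n_individuals = n_individuals, n_steps = n_steps,
            extinction_coef = extinction_coef, mutation_sd = mutation_sd,
            speciation_coef = speciation_coef, reflect = reflect)
  num <- p[setdiff(names(p), "reflect")]
  if (any(!vapply(num, is.numeric, logical(1))) || any(unlist(num) <= 0))
    stop("all pool parameters must be positive numbers")
  structure(p, class = "pool_params")
}

#' @keywords internal
#' Fold values into [0, 1] by reflection at both boundaries.
reflect01 <- function(x) {
  x <- x %% 2
  ifelse(x > 1, 2 - x, x)
}

#' Evolve a regional species pool
#'
#' Runs the diversification model of [pool_params()] from a single ancestor
#' with a uniform-random environmental optimum, recording the genealogy
#' (converted to a dated phylogeny with branch lengths in time steps) and
#' each extant species' niche optimum.
#'
#' @param params a [pool_params()] object.
#' @param seed optional integer seed.
#' @return object of class `"regional_pool"`: `species` (full records:
#'   id, parent, birth, death, optimum), `taxon_ids` and `optima` for the
#'   extant species, `richness`, `richness_trajectory` (richness after every
#'   step), `phylo` (ape tree over extant species), and `params`.
#' @export
evolve_pool <- function(params = pool_params(), seed = NULL) {
  stopifnot(inherits(params, "pool_params"))
  with_seed_(seed, {
    cap <- 4096L
    parent <- birth <- death <- integer(cap)
    optimum <- numeric(cap)
    alive <- logical(cap)
    n_sp <- 1L
    parent[1L] <- NA_integer_; birth[1L] <- 0L; death[1L] <- NA_integer_
    optimum[1L] <- stats::runif(1)
    alive[1L] <- TRUE
    richness_trajectory <- integer(params$n_steps)
    for (step in seq_len(params$n_steps)) {
      ext <- which(alive[seq_len(n_sp)])
      S <- length(ext)
      N <- params$n_individuals / S
      # speciation (probability from start-of-step population size)
      p_spec <- 1 - exp(-params$speciation_coef * N)
      parents <- ext[stats::runif(S) < p_spec]
      if (length(parents)) {
        k <- length(parents)
        while (n_sp + k > cap) {
          cap <- cap * 2L
          length(parent) <- cap; length(birth) <- cap; length(death) <- cap
          length(optimum) <- cap; length(alive) <- cap
          alive[is.na(alive)] <- FALSE
        }
        idx <- n_sp + seq_len(k)
        parent[idx] <- parents
        birth[idx] <- step
        step_opt <- optimum[parents] + stats::rnorm(k, 0, params$mutation_sd)
        optimum[idx] <- if (params$reflect) reflect01(step_opt)
                        else pmin(1, pmax(0, step_opt))
        death[idx] <- NA_integer_
        alive[idx] <- TRUE
        n_sp <- n_sp + k
      }
      # extinction (probability from post-speciation, re-equalized sizes)
      ext <- which(alive[seq_len(n_sp)])
      N2 <- params$n_individuals / length(ext)
      dies <- ext[stats::runif(length(ext)) < exp(-params$extinction_coef * N2)]
      if (length(dies) == length(ext))
        stop("total extinction of the regional pool at step ", step,
             "; rerun with a different seed")
      if (length(dies)) {
        alive[dies] <- FALSE
        death[dies] <- step
      }
      richness_trajectory[step] <- sum(alive[seq_len(n_sp)])
    }
    sp <- data.frame(id = seq_len(n_sp), parent = parent[seq_len(n_sp)],
                     birth = birth[seq_len(n_sp)], death = death[seq_len(n_sp)],
                     optimum = optimum[seq_len(n_sp)])
    extant <- which(alive[seq_len(n_sp)])
    pool <- structure(list(species = sp,
                           taxon_ids = paste0("sp", extant),
                           optima = stats::setNames(sp$optimum[extant],
                                                    paste0("sp", extant)),
                           richness = length(extant),
                           richness_trajectory = richness_trajectory,
                           phylo = NULL, params = params),
                      class = "regional_pool")
    pool$phylo <- pool_phylogeny(pool)
    pool
  })
}

#' Genealogy of the extant species as a dated phylogeny
#'
#' Speciation is budding (the parent persists and the child starts a new
#' lineage), so internal nodes are placed at the birth times of descendants
#' that left extant progeny; branch lengths accrue one unit per time step
#' survived and all extant tips are contemporaneous.
#'
#' @param pool a [evolve_pool()] result.
#' @return `ape::phylo` tree whose tips are the extant species.
#' @export
pool_phylogeny <- function(pool) {
  sp <- pool$species
  n <- nrow(sp)
  if (pool$richness < 2)
    stop("need at least 2 extant species to build a phylogeny")
  t_end <- pool$params$n_steps
  extant <- is.na(sp$death)
  retained <- extant
  for (i in rev(seq_len(n)))  # children always have larger ids than parents
    if (retained[i] && !is.na(sp$parent[i]))
      retained[sp$parent[i]] <- TRUE
  kids <- vector("list", n)
  for (i in which(retained & !is.na(sp$parent))) {
    p <- sp$parent[i]
    kids[[p]] <- c(kids[[p]], i)   # ids are in birth order already
  }
  # Recursive newick assembly over retained lineage segments. g(s, ci, t0)
  # renders species s's lineage from time t0 onward, with ci indexing the
  # next retained child; returns list(str, len) or NULL for a dead end.
  g <- function(s, ci, t0) {
    ks <- kids[[s]]
    if (ci > length(ks)) {
      if (extant[s]) return(list(str = paste0("sp", s), len = t_end - t0))
      return(NULL)
    }
    child <- ks[ci]
    tc <- sp$birth[child]
    rest <- g(s, ci + 1L, tc)
    sub <- g(child, 1L, tc)
    if (is.null(rest) && is.null(sub)) return(NULL)
    if (is.null(rest)) return(list(str = sub$str, len = sub$len + tc - t0))
    if (is.null(sub)) return(list(str = rest$str, len = rest$len + tc - t0))
    list(str = paste0("(", rest$str, ":", rest$len, ",",
                      sub$str, ":", sub$len, ")"),
         len = tc - t0)
  }
  root <- g(1L, 1L, sp$birth[1L])
  tree <- ape::read.tree(text = paste0(root$str, ";"))
  check_phylogeny(tree)
  tree
}

#' @export
print.regional_pool <- function(x, ...) {
  cat("regional_pool: ", x$richness, " extant species after ",
      x$params$n_steps, " steps (", format(x$params$n_individuals,
      scientific = FALSE), " individuals)\n", sep = "")
  invisible(x)
}

#' Mantel test of phylogenetic signal in niche optima
#'
#' Tests whether phylogenetically close species have similar environmental
#' optima by permutationally correlating the patristic distance matrix with
#' the matrix of absolute optimum differences. Significant positive
#' correlation is the prerequisite for reading phylogenetic turnover as a
#' signature of selection.
#'
#' @param pool a [evolve_pool()] result (or any list with `phylo` and named
#'   `optima`).
#' @param n_perm Mantel permutations (default 199).
#' @param max_species subsample at most this many species to bound the cost
#'   of the permutation test (default 400).
#' @param seed optional integer seed (controls subsampling and permutations).
#' @return list with `statistic` (Mantel r) and `p_value`.
#' @export
phylogenetic_signal <- function(pool, n_perm = 199, max_species = 400,
                                seed = NULL) {
  opt <- pool$optima
  if (length(opt) < 10) stop("need at least 10 species")
  if (stats::sd(opt) == 0) stop("degenerate: all niche optima are equal")
  with_seed_(seed, {
    ids <- names(opt)
    if (length(ids) > max_species) ids <- sample(ids, max_species)
    tr <- ape::keep.tip(pool$phylo, ids)
    d_phy <- stats::as.dist(cophenetic_distances(tr)[ids, ids])
    d_opt <- stats::dist(opt[ids])
    mt <- vegan::mantel(d_phy, d_opt, method = "pearson",
                        permutations = n_perm)
    list(statistic = unname(mt$statistic), p_value = mt$signif,
         n_species = length(ids), n_perm = n_perm)
  })
}
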