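#' Patristic (cophenetic) distance matrix of a phylogeny
#'
#' Sums branch lengths along the tree path between every pair of tips.
#'
#' @param tree rooted `ape::phylo` tree with branch lengths.
#' @return symmetric numeric matrix over the tips, zero diagonal.
#' @export
cophenetic_distances <- function(tree) {
  check_phylogeny(tree)
  stats::cophenetic(tree)
}

#' @keywords internal
#' Extract present taxa and within-community relative abundances.
community_weights <- function(x, abundance_weighted = TRUE) {
  if (is.null(names(x))) stop("community vector must be named by taxon")
  x <- x[x > 0]
  if (!length(x)) stop("empty community (no positive abundances)")
  f <- if (abundance_weighted) x / sum(x) else rep(1 / length(x), length(x))
  list(taxa = names(x), f = unname(f))
}

#' Between-community mean nearest taxon distance (bMNTD)
#'
#' For each taxon in one community, finds the phylogenetic distance to its
#' closest relative in the other community; bMNTD is half the sum of the two
#' directed abundance-weighted means:
#' \deqn{0.5 [ \sum_i f_{ik} \min_j \Delta_{i_k j_m} +
#'             \sum_i f_{im} \min_j \Delta_{i_m j_k} ]}
#' where \eqn{f_{ik}} is the relative abundance of taxon \eqn{i} within
#' community \eqn{k}. With `abundance_weighted = FALSE` each present taxon
#' gets weight 1/richness.
#'
#' @param x,y named abundance vectors (taxon names must index `dmat`).
#' @param dmat patristic distance matrix from [cophenetic_distances()].
#' @param abundance_weighted weight taxa by relative abundance (default) or
#'   equally.
#' @return a single nonnegative number.
#' @export
beta_mntd <- function(x, y, dmat, abundance_weighted = TRUE) {
  cx <- community_weights(x, abundance_weighted)
  cy <- community_weights(y, abundance_weighted)
  miss <- setdiff(c(cx$taxa, cy$taxa), rownames(dmat))
  if (length(miss))
    stop("taxa missing from the distance matrix: ", paste(miss, collapse = ", "))
  ik <- match(cx$taxa, rownames(dmat)) - 1L
  im <- match(cy$taxa, rownames(dmat)) - 1L
  .bmntd_pair_cpp(dmat, ik, im, cx$f, cy$f)
}

#' Beta nearest taxon index (bNTI): tip-shuffle null model for bMNTD
#'
#' Generates a null distribution of bMNTD by permuting taxon identities across
#' the tips of the phylogeny (implemented as label permutations of the
#' patristic matrix over a configurable taxon pool) while abundances stay
#' fixed, then standardizes the observed value:
#' \deqn{bNTI = (bMNTD_{obs} - \bar{bMNTD}_{null}) / sd(bMNTD_{null})}
#' Values below -2 or above +2 are conventionally taken as significant
#' phylogenetic turnover (homogeneous or variable selection respectively).
#'
#' @inheritParams beta_mntd
#' @param pool character vector of taxon names over which tip identities are
#'   shuffled; must contain every taxon present in `x` or `y`. Defaults to the
#'   union of the pair's taxa; callers analysing a metacommunity group
#'   typically pass the group-wide taxon union (see [run_inference()]).
#' @param n_null number of null replicates (default 999).
#' @param seed optional integer seed for the permutation stream; `NULL` uses
#'   (and advances) the current RNG state.
#' @return object of class `"null_comparison"` with elements `observed`,
#'   `null` (vector of replicate values), `score`, `n_null`, `metric`.
#' @export
beta_nti <- function(x, y, dmat, pool = NULL, n_null = 999, seed = NULL,
                     abundance_weighted = TRUE) {
  if (n_null < 2) stop("n_null must be at least 2")
  cx <- community_weights(x, abundance_weighted)
  cy <- community_weights(y, abundance_weighted)
  if (is.null(pool)) pool <- union(cx$taxa, cy$taxa)
  miss <- setdiff(c(cx$taxa, cy$taxa), pool)
  if (length(miss))
    stop("null pool must contain all taxa of both communities; missing: ",
         paste(miss, collapse = ", "))
  miss <- setdiff(pool, rownames(dmat))
  if (length(miss))
    stop("taxa missing from the distance matrix: ", paste(miss, collapse = ", "))
  pool_idx <- match(pool, rownames(dmat)) - 1L
  posk <- match(cx$taxa, pool) - 1L
  posm <- match(cy$taxa, pool) - 1L
  observed <- .bmntd_pair_cpp(dmat, pool_idx[posk + 1L], pool_idx[posm + 1L],
                              cx$f, cy$f)
  P <- length(pool)
  perms <- with_seed_(seed,
    vapply(seq_len(n_null), function(r) sample.int(P), integer(P))) - 1L
  nulls <- .bmntd_null_cpp(dmat, pool_idx, perms, posk, posm, cx$f, cy$f)
  s <- stats::sd(nulls)
  if (s == 0)
    stop("degenerate null distribution (sd = 0) for pair; ",
         "all pool permutations give identical bMNTD")
  structure(list(metric = "bNTI", observed = observed, null = nulls,
                 score = (observed - mean(nulls)) / s, n_null = n_null),
            class = "null_comparison")
}

#' @export
print.null_comparison <- function(x, ...) {
  cat(x$metric, ": observed = ", format(x$observed), ", score = ",
      format(x$score), " (", x$n_null, " nulls)\n", sep = "")
  invisible(x)
}
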