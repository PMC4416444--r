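#' Bray-Curtis dissimilarity between two abundance vectors
#'
#' \eqn{\sum_i |x_i - y_i| / \sum_i (x_i + y_i)} on the supplied scale
#' (counts are used as-is). Ranges from 0 (identical) to 1 (disjoint
#' supports).
#'
#' @param x,y numeric vectors on a common taxon list; if both are named the
#'   names must match as sets and `y` is aligned to `x`.
#' @return dissimilarity in `[0, 1]`.
#' @export
bray_curtis <- function(x, y) {
  if (!is.null(names(x)) && !is.null(names(y))) {
    if (!setequal(names(x), names(y)))
      stop("x and y are named on different taxon sets")
    y <- y[names(x)]
  } else if (length(x) != length(y)) {
    stop("x and y must be aligned on the same taxon list")
  }
  if (any(x < 0) || any(y < 0)) stop("negative abundances")
  tot <- sum(x) + sum(y)
  if (tot == 0) stop("both communities are empty")
  sum(abs(x - y)) / tot
}

#' Metacommunity occupancy and pooled-abundance profile
#'
#' Summarizes a group of local communities for stochastic null assembly:
#' each taxon's occupancy (number of local communities in which it occurs)
#' and its pooled relative abundance across all communities of the group.
#' Taxa never observed in the group are dropped.
#'
#' @param comm community matrix (samples x taxa) for one metacommunity group.
#' @return object of class `"metacommunity_profile"`.
#' @export
metacommunity_profile <- function(comm) {
  m <- unclass(comm)
  attr(m, "group") <- NULL
  occ <- colSums(m > 0)
  keep <- occ > 0
  pooled <- colSums(m)[keep]
  structure(list(taxon_ids = colnames(m)[keep],
                 occupancy = unname(occ[keep]),
                 pooled_abundance = unname(pooled / sum(pooled)),
                 n_samples = nrow(m)),
            class = "metacommunity_profile")
}

#' Stochastically assemble one null community from a metacommunity profile
#'
#' Draws `target_richness` distinct taxa with probabilities proportional to
#' occupancy, seeds each with one individual, then distributes the remaining
#' individuals multinomially with probabilities proportional to pooled
#' relative abundance (renormalized over the drawn taxa). This emulates
#' assembly under weak selection and random dispersal while conserving the
#' observed richness and total abundance.
#'
#' Uses (and advances) the current RNG stream; callers control seeding.
#'
#' @param profile a [metacommunity_profile()].
#' @param target_richness number of taxa to draw.
#' @param target_total total number of individuals (integer,
#'   `>= target_richness`).
#' @return named integer-valued vector over the profile's taxa.
#' @export
null_assemble <- function(profile, target_richness, target_total) {
  nt <- length(profile$taxon_ids)
  if (target_richness > nt)
    stop("target richness ", target_richness, " exceeds pool richness ", nt)
  if (target_richness < 1) stop("target richness must be positive")
  if (target_total < target_richness)
    stop("target total must be at least the target richness")
  idx <- if (target_richness == nt) seq_len(nt)
         else sample.int(nt, target_richness, prob = profile$occupancy)
  out <- numeric(nt)
  names(out) <- profile$taxon_ids
  p <- profile$pooled_abundance[idx]
  extra <- target_total - target_richness
  out[idx] <- 1 + if (extra > 0)
    as.numeric(stats::rmultinom(1L, extra, p / sum(p))) else 0
  out
}

#' Abundance-based Raup-Crick score (RC-bray)
#'
#' Compares the observed Bray-Curtis dissimilarity of a pair of communities
#' to a null distribution in which both communities are independently
#' re-assembled by [null_assemble()] (each conserving its own observed
#' richness and total abundance). The score is the rescaled percentile
#' position of the observation:
#' \deqn{RC = 2\,[(\#\{null < obs\} + 0.5\,\#\{null = obs\}) / n_{null} - 0.5]}
#' so RC is in `[-1, +1]`; pairs more similar than expected by chance
#' approach -1 (homogenizing dispersal) and pairs more different approach +1
#' (dispersal limitation). Ties are defined with an absolute tolerance on the
#' Bray-Curtis values.
#'
#' @param x,y named integer-valued abundance vectors (counts); all present
#'   taxa must belong to the profile.
#' @param profile a [metacommunity_profile()] for the pair's metacommunity
#'   group.
#' @param n_null number of null replicates (default 999).
#' @param seed optional integer seed; `NULL` uses the current RNG state.
#' @param tie_tol absolute tolerance declaring two dissimilarities tied.
#' @return object of class `"null_comparison"`.
#' @export
rc_bray <- function(x, y, profile, n_null = 999, seed = NULL,
                    tie_tol = 1e-10) {
  if (n_null < 2) stop("n_null must be at least 2")
  x <- x[x > 0]; y <- y[y > 0]
  if (!length(x) || !length(y)) stop("empty community")
  miss <- setdiff(union(names(x), names(y)), profile$taxon_ids)
  if (length(miss))
    stop("taxa absent from the metacommunity profile: ",
         paste(miss, collapse = ", "))
  totx <- sum(x); toty <- sum(y)
  if (max(abs(c(totx, toty) - round(c(totx, toty)))) > 1e-8)
    stop("RC-bray requires count data (integer totals)")
  rx <- length(x); ry <- length(y)
  if (length(profile$taxon_ids) == 1L && max(rx, ry) > 1L)
    stop("degenerate profile: single taxon in pool")
  xv <- yv <- numeric(length(profile$taxon_ids))
  names(xv) <- names(yv) <- profile$taxon_ids
  xv[names(x)] <- x; yv[names(y)] <- y
  observed <- bray_curtis(unname(xv), unname(yv))
  nulls <- with_seed_(seed, vapply(seq_len(n_null), function(r) {
    nx <- null_assemble(profile, rx, round(totx))
    ny <- null_assemble(profile, ry, round(toty))
    sum(abs(nx - ny)) / (totx + toty)
  }, numeric(1)))
  n_less <- sum(nulls < observed - tie_tol)
  n_tie <- sum(abs(nulls - observed) <= tie_tol)
  structure(list(metric = "RC_bray", observed = observed, null = nulls,
                 score = 2 * ((n_less + 0.5 * n_tie) / n_null - 0.5),
                 n_null = n_null),
            class = "null_comparison")
}
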