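#' The five assembly-process categories
#' @export
process_categories <- function() {
  c("variable_selection", "homogeneous_selection", "dispersal_limitation",
    "homogenizing_dispersal", "undominated")
}

#' Classify a pairwise comparison into an assembly-process category
#'
#' Selection is evaluated first from the phylogenetic score: `bnti > +t`
#' indicates variable selection, `bnti < -t` homogeneous selection. Only when
#' `|bnti| < t` is the taxonomic score consulted: `rc > +r` indicates
#' dispersal limitation, `rc < -r` homogenizing dispersal, and anything else
#' is undominated. All inequalities are strict, so scores exactly at a
#' threshold fall through to the next tier.
#'
#' @param bnti,rc numeric vectors of bNTI and RC-bray scores (recycled to a
#'   common length); must be finite.
#' @param bnti_threshold,rc_threshold significance thresholds (defaults 2 and
#'   0.95).
#' @return factor with levels [process_categories()].
#' @export
classify_pair <- function(bnti, rc, bnti_threshold = 2, rc_threshold = 0.95) {
  if (bnti_threshold <= 0 || rc_threshold <= 0) stop("thresholds must be positive")
  n <- max(length(bnti), length(rc))
  bnti <- rep_len(bnti, n); rc <- rep_len(rc, n)
  if (anyNA(bnti) || anyNA(rc) || any(!is.finite(bnti)) || any(!is.finite(rc)))
    stop("scores must be finite (no NA/NaN)")
  out <- rep("undominated", n)
  out[bnti > bnti_threshold] <- "variable_selection"
  out[bnti < -bnti_threshold] <- "homogeneous_selection"
  sel <- abs(bnti) < bnti_threshold | abs(bnti) == bnti_threshold
  out[sel & rc > rc_threshold] <- "dispersal_limitation"
  out[sel & rc < -rc_threshold] <- "homogenizing_dispersal"
  factor(out, levels = process_categories())
}

#' Per-sample process-influence fractions from pairwise calls
#'
#' For each focal sample, the relative influence of each assembly process is
#' the fraction of that sample's pairwise comparisons assigned to the
#' corresponding category; the five fractions sum to 1.
#'
#' @param calls data.frame with columns `sample_a`, `sample_b`, `category`.
#' @param focal optional single sample id; default computes fractions for
#'   every sample appearing in `calls`.
#' @return data.frame with `sample_id`, one column per category, and
#'   `n_comparisons`.
#' @export
process_fractions <- function(calls, focal = NULL) {
  stopifnot(all(c("sample_a", "sample_b", "category") %in% colnames(calls)))
  cats <- process_categories()
  samples <- if (is.null(focal)) sort(unique(c(as.character(calls$sample_a),
                                               as.character(calls$sample_b))))
             else as.character(focal)
  rows <- lapply(samples, function(s) {
    sub <- calls[calls$sample_a == s | calls$sample_b == s, , drop = FALSE]
    if (!nrow(sub)) stop("no comparisons found for focal sample '", s, "'")
    counts <- table(factor(as.character(sub$category), levels = cats))
    data.frame(sample_id = s, as.list(counts / nrow(sub)),
               n_comparisons = nrow(sub), check.names = FALSE,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' End-to-end process inference for a community table
#'
#' For every pair of samples within each metacommunity group, computes bNTI
#' ([beta_nti()]) and RC-bray ([rc_bray()]), classifies the pair
#' ([classify_pair()]), and aggregates per-sample process-influence fractions
#' ([process_fractions()]). Null-model pools (taxon shuffle pool, occupancy
#' profile) are built per group. Results are deterministic for a fixed
#' `seed`: each pair's null streams are derived from the root seed by stable
#' hashing of the ordered pair ids, so sample order does not affect scores.
#'
#' @param comm community matrix of counts (samples x taxa).
#' @param tree rooted phylogeny covering all taxa (extra tips are pruned).
#' @param meta optional metadata (checked for the spatial stage only).
#' @param groups optional per-sample group labels; defaults to the matrix's
#'   `group` attribute, else a single group.
#' @param n_null null replicates for both metrics.
#' @param seed root seed.
#' @param null_pool taxon pool for the tip shuffle: union of taxa observed in
#'   the group (default), only the pair, or all tree tips.
#' @param bnti_threshold,rc_threshold classification thresholds.
#' @param abundance_weighted weight bMNTD by relative abundances.
#' @return list of class `"assembly_inference"` with data.frames `pairs` and
#'   `fractions`.
#' @export
run_inference <- function(comm, tree, meta = NULL, groups = NULL,
                          n_null = 999, seed = 1,
                          null_pool = c("group-union", "pair-union", "all-tips"),
                          bnti_threshold = 2, rc_threshold = 0.95,
                          abundance_weighted = TRUE) {
  null_pool <- match.arg(null_pool)
  rep <- validate_inputs(comm, tree, meta)
  if (!rep$phylo_ok)
    stop("taxa absent from the phylogeny: ",
         paste(rep$missing_from_tree, collapse = ", "))
  if (length(rep$extra_tips)) tree <- ape::keep.tip(tree, colnames(comm))
  dmat <- cophenetic_distances(tree)
  grp <- sample_groups(comm, groups)
  pair_rows <- list()
  for (g in unique(grp)) {
    ids <- sort(rownames(comm)[grp == g])
    if (length(ids) < 2) next
    sub <- unclass(comm)[ids, , drop = FALSE]
    profile <- metacommunity_profile(sub)
    pool <- switch(null_pool,
      "group-union" = colnames(sub)[colSums(sub) > 0],
      "all-tips" = tree$tip.label,
      "pair-union" = NULL)
    for (i in seq_len(length(ids) - 1L)) for (j in seq.int(i + 1L, length(ids))) {
      a <- ids[i]; b <- ids[j]
      bn <- beta_nti(sub[a, ], sub[b, ], dmat, pool = pool, n_null = n_null,
                     seed = pair_seed(seed, "bnti", a, b),
                     abundance_weighted = abundance_weighted)
      rc <- rc_bray(sub[a, ], sub[b, ], profile, n_null = n_null,
                    seed = pair_seed(seed, "rc", a, b))
      pair_rows[[length(pair_rows) + 1L]] <- data.frame(
        sample_a = a, sample_b = b, group = g,
        bMNTD_obs = bn$observed, null_mean = mean(bn$null),
        null_sd = stats::sd(bn$null), bNTI = bn$score,
        bray_obs = rc$observed, rc_bray = rc$score,
        stringsAsFactors = FALSE)
    }
  }
  if (!length(pair_rows)) stop("no group has at least two samples")
  pairs <- do.call(rbind, pair_rows)
  pairs$category <- classify_pair(pairs$bNTI, pairs$rc_bray,
                                  bnti_threshold, rc_threshold)
  fractions <- do.call(rbind, lapply(unique(pairs$group), function(g) {
    fr <- process_fractions(pairs[pairs$group == g, , drop = FALSE])
    fr$group <- g
    fr
  }))
  rownames(pairs) <- rownames(fractions) <- NULL
  structure(list(pairs = pairs, fractions = fractions,
                 n_null = n_null, seed = seed, null_pool = null_pool),
            class = "assembly_inference")
}

#' @export
print.assembly_inference <- function(x, ...) {
  cat("assembly process inference: ", nrow(x$pairs), " pairs, ",
      nrow(x$fractions), " samples (", x$n_null, " nulls, pool = ",
      x$null_pool, ")\n", sep = "")
  invisible(x)
}
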