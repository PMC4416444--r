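#' Expectations for the seven-community benchmark comparisons
#'
#' Each tabulated comparison has a primary expected process call and a
#' secondary call that absorbs the most likely failure mode of the primary
#' (e.g., weak selection occasionally constraining composition enough to
#' register as homogeneous selection).
#'
#' @return data.frame with columns `comparison`, `pair_a`, `pair_b`,
#'   `primary`, `secondary`.
#' @export
scenario_expectations <- function() {
  data.frame(
    comparison = c("1-2", "1-3", "1-4", "1-5", "1-(6|7)", "1-(6|7)", "6-7"),
    pair_a = c("C1", "C1", "C1", "C1", "C1", "C1", "C6"),
    pair_b = c("C2", "C3", "C4", "C5", "C6", "C7", "C7"),
    primary = c("homogenizing_dispersal", "undominated",
                "dispersal_limitation", "homogenizing_dispersal",
                "variable_selection", "variable_selection",
                "homogeneous_selection"),
    secondary = c("homogeneous_selection", "homogeneous_selection",
                  "homogeneous_selection", "variable_selection",
                  "dispersal_limitation", "dispersal_limitation",
                  "dispersal_limitation"),
    stringsAsFactors = FALSE)
}

#' Run the scenario-based validation of the inference framework
#'
#' Repeatedly assembles the seven benchmark communities from one evolved
#' regional pool, computes bNTI (tip-shuffle null on the pool genealogy) and
#' RC-bray (null assembly from the seven-community metacommunity profile) for
#' the six tabulated comparisons, classifies each with [classify_pair()], and
#' reports the fraction of iterations matching the primary expectation, the
#' secondary expectation, or neither. The two comparisons against the
#' red-environment no-dispersal communities (1 vs 6 and 1 vs 7) are pooled
#' into a single row by default.
#'
#' @param pool a [evolve_pool()] result.
#' @param n_iter number of assembly iterations (default 1000; 200 gives
#'   roughly +/-6 percentage points of binomial sampling error at rates near
#'   0.9).
#' @param n_null null replicates per metric (default 999).
#' @param seed optional integer seed.
#' @param null_pool taxon pool for the tip shuffle (see [run_inference()]);
#'   the default shuffles across the union of taxa observed in the seven
#'   communities.
#' @param pool_67 combine the 1 vs 6 and 1 vs 7 comparisons by pooling both
#'   into one denominator (default) or by averaging their two rates.
#' @return data.frame of class `"validation_matrix"`: one row per comparison
#'   with `fraction_primary`, `fraction_secondary`, `fraction_unexpected`,
#'   and `n` (number of pooled comparisons).
#' @export
run_validation <- function(pool, n_iter = 1000, n_null = 999, seed = NULL,
                           null_pool = c("group-union", "pair-union",
                                         "all-tips"),
                           pool_67 = c("pooled", "averaged")) {
  null_pool <- match.arg(null_pool)
  pool_67 <- match.arg(pool_67)
  exp_tab <- scenario_expectations()
  dmat <- cophenetic_distances(pool$phylo)
  counts <- matrix(0L, nrow(exp_tab), 3L,
                   dimnames = list(NULL, c("primary", "secondary", "unexpected")))
  with_seed_(seed, {
    for (iter in seq_len(n_iter)) {
      comm <- assemble_scenarios(pool)
      profile <- metacommunity_profile(comm)
      shuffle_pool <- switch(null_pool,
        "group-union" = colnames(comm)[colSums(comm) > 0],
        "all-tips" = rownames(dmat),
        "pair-union" = NULL)
      for (r in seq_len(nrow(exp_tab))) {
        a <- comm[exp_tab$pair_a[r], ]; b <- comm[exp_tab$pair_b[r], ]
        bn <- beta_nti(a, b, dmat, pool = shuffle_pool, n_null = n_null)
        rc <- rc_bray(a, b, profile, n_null = n_null)
        cat_r <- as.character(classify_pair(bn$score, rc$score))
        col <- if (cat_r == exp_tab$primary[r]) "primary"
               else if (cat_r == exp_tab$secondary[r]) "secondary"
               else "unexpected"
        counts[r, col] <- counts[r, col] + 1L
      }
    }
  })
  rows <- split(seq_len(nrow(exp_tab)), exp_tab$comparison)
  agg <- lapply(rows, function(ix) {
    cm <- counts[ix, , drop = FALSE]
    if (length(ix) > 1L && pool_67 == "averaged") {
      fr <- colMeans(cm / rowSums(cm))
      n <- sum(cm)
    } else {
      cs <- colSums(cm)
      fr <- cs / sum(cs)
      n <- sum(cs)
    }
    data.frame(comparison = exp_tab$comparison[ix[1L]],
               primary_process = exp_tab$primary[ix[1L]],
               secondary_process = exp_tab$secondary[ix[1L]],
               fraction_primary = unname(fr["primary"]),
               fraction_secondary = unname(fr["secondary"]),
               fraction_unexpected = unname(fr["unexpected"]),
               n = n, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, agg)
  ord <- c("1-2", "1-3", "1-4", "1-5", "1-(6|7)", "6-7")
  out <- out[match(ord, out$comparison), ]
  rownames(out) <- NULL
  attr(out, "n_iter") <- n_iter
  attr(out, "n_null") <- n_null
  class(out) <- c("validation_matrix", "data.frame")
  out
}
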