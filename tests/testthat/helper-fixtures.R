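# Shared builders for small in-code fixtures. All randomized helpers take an
# explicit seed so tests are reproducible.

toy_tree <- function() read_phylogeny("((A:1,B:1):1,C:2);")

quartet_tree <- function() {
  read_phylogeny("((A:0.5,C:0.5):0.5,(B:0.5,D:0.5):0.5);")
}

# Rooted binary tree with zero-length internal edges: every pair of tips is
# at patristic distance 2L, like a star tree, but satisfies ape's rootedness.
star_tree <- function(n = 4, L = 1) {
  nwk <- paste0("t", n, ":", L)
  for (i in rev(seq_len(n - 1L)))
    nwk <- paste0("(t", i, ":", L, ",", nwk, if (i == 1L) ");" else "):0")
  read_phylogeny(nwk)
}

toy_comm <- function() {
  m <- matrix(c(5, 3, 0, 2,
                0, 4, 4, 0,
                1, 0, 2, 7), nrow = 3, byrow = TRUE,
              dimnames = list(c("S1", "S2", "S3"), c("A", "B", "C", "D")))
  community_matrix(m)
}

random_tree <- function(n, seed) {
  set.seed(seed)
  tr <- ape::rtree(n)
  tr$edge.length <- abs(tr$edge.length)
  tr
}

# Brute-force patristic distance: walk both tips' paths to the root and sum
# the branch lengths not shared between the paths.
brute_cophenetic <- function(tree) {
  ntip <- length(tree$tip.label)
  root <- ntip + 1L
  parent_of <- integer(max(tree$edge))
  len_to_parent <- numeric(max(tree$edge))
  parent_of[tree$edge[, 2]] <- tree$edge[, 1]
  len_to_parent[tree$edge[, 2]] <- tree$edge.length
  path_to_root <- function(node) {
    path <- node
    while (node != root) {
      node <- parent_of[node]
      path <- c(path, node)
    }
    path
  }
  D <- matrix(0, ntip, ntip, dimnames = list(tree$tip.label, tree$tip.label))
  for (i in seq_len(ntip - 1L)) for (j in seq.int(i + 1L, ntip)) {
    pi <- path_to_root(i); pj <- path_to_root(j)
    shared <- intersect(pi, pj)
    d <- sum(len_to_parent[setdiff(pi, shared)]) +
      sum(len_to_parent[setdiff(pj, shared)])
    D[i, j] <- D[j, i] <- d
  }
  D
}

# Independent bMNTD oracle: exhaustive min-search with plain loops.
naive_bmntd <- function(x, y, D, abundance_weighted = TRUE) {
  tx <- names(x)[x > 0]; ty <- names(y)[y > 0]
  fx <- if (abundance_weighted) x[tx] / sum(x[tx]) else rep(1 / length(tx), length(tx))
  fy <- if (abundance_weighted) y[ty] / sum(y[ty]) else rep(1 / length(ty), length(ty))
  sx <- 0
  for (i in seq_along(tx)) {
    best <- Inf
    for (j in seq_along(ty)) best <- min(best, D[tx[i], ty[j]])
    sx <- sx + fx[i] * best
  }
  sy <- 0
  for (j in seq_along(ty)) {
    best <- Inf
    for (i in seq_along(tx)) best <- min(best, D[tx[i], ty[j]])
    sy <- sy + fy[j] * best
  }
  unname(0.5 * (sx + sy))
}

# Random community pair over the tips of a tree.
random_pair <- function(tree, seed, n_taxa = NULL) {
  set.seed(seed)
  tips <- tree$tip.label
  if (is.null(n_taxa)) n_taxa <- max(2L, length(tips) %/% 2L)
  mk <- function() {
    v <- numeric(length(tips)); names(v) <- tips
    sel <- sample(tips, n_taxa)
    v[sel] <- rpois(n_taxa, 8) + 1
    v
  }
  list(x = mk(), y = mk())
}

# Scaled-down pool for simulator tests: same dynamics, ~220-species
# equilibrium instead of ~1100 (comfortably above the 100 species each
# assembled community draws).
small_pool_params <- function() {
  pool_params(n_individuals = 4e5, n_steps = 80)
}

# Direct eigen-decomposition oracle for the spatial eigenbasis: truncate the
# distance matrix at the longest minimum-spanning-tree edge, Gower
# double-center, decompose, keep positive axes scaled by sqrt(eigenvalue).
pcnm_oracle <- function(coords, mult = 4) {
  d <- as.matrix(stats::dist(coords))
  thr <- max(vegan::spantree(stats::dist(coords))$dist)
  d[d > thr] <- mult * thr
  a <- -0.5 * d^2
  g <- a - outer(rowMeans(a), colMeans(a), "+") + mean(a)
  e <- eigen(g, symmetric = TRUE)
  keep <- e$values > sqrt(.Machine$double.eps) * max(abs(e$values))
  list(values = e$values[keep],
       vectors = sweep(e$vectors[, keep, drop = FALSE], 2,
                       sqrt(e$values[keep]), "*"))
}
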