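#' Write a self-contained synthetic dataset for the inference pipeline
#'
#' Evolves a regional pool, assembles replicate sets of the seven benchmark
#' communities, and writes the three files consumed by [run_inference()] and
#' the spatial stage: a taxa-by-samples community table, the pool genealogy
#' in newick, and sample metadata with synthetic planar coordinates and
#' environmental features (the niche-axis environment value of each
#' community, plus a distance-like covariate derived from the coordinates).
#' All samples are placed in a single metacommunity group.
#'
#' @param dir output directory (created if needed).
#' @param params a [pool_params()]; the defaults are the full-scale study
#'   conditions, tests typically pass a scaled-down configuration.
#' @param n_replicates replicate scenario sets to assemble (default 2, giving
#'   14 samples).
#' @param seed integer seed; the same seed reproduces identical files.
#' @return invisibly, named character vector of the three file paths.
#' @export
make_fixture <- function(dir, params = pool_params(), n_replicates = 2,
                         seed = 1) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  pool <- evolve_pool(params, seed = seed)
  comm_list <- lapply(seq_len(n_replicates), function(r) {
    m <- assemble_scenarios(pool, seed = pair_seed(seed, "fixture", r))
    rownames(m) <- paste0(rownames(m), "_r", r)
    unclass(m)
  })
  m <- do.call(rbind, comm_list)
  m <- m[, colSums(m) > 0, drop = FALSE]
  comm <- community_matrix(m)
  tree <- ape::keep.tip(pool$phylo, colnames(m))

  env_value <- rep(rep(c(0.05, 0.05, 0.05, 0.05, 0.95, 0.95, 0.95),
                       n_replicates))
  meta <- with_seed_(pair_seed(seed, "fixture-meta"), {
    n <- nrow(m)
    x <- stats::runif(n, 0, 100)
    y <- stats::runif(n, 0, 100)
    data.frame(sample_id = rownames(m), x = x, y = y,
               env_value = env_value,
               dist_river = 100 - x,
               layer_thickness = 5 + 0.05 * y + stats::rnorm(n, 0, 0.5),
               stringsAsFactors = FALSE)
  })

  paths <- c(community = file.path(dir, "community.tsv"),
             tree = file.path(dir, "tree.nwk"),
             metadata = file.path(dir, "metadata.tsv"))
  write_community_table(comm, paths[["community"]], orientation = "taxa_rows")
  write_phylogeny(tree, paths[["tree"]])
  write_sample_metadata(meta, paths[["metadata"]])
  invisible(paths)
}
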