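test_that("Gaussian fitness kernels match their closed forms", {
  blue <- blue_environment(); red <- red_environment()
  expect_equal(gaussian_fitness(0.05, blue), 1)
  expect_equal(gaussian_fitness(0.95, red), 1)
  # one 'natural' unit from the optimum: exp(-1)
  expect_equal(gaussian_fitness(0.05 + sqrt(0.35), blue), exp(-1))
  # narrower kernel means stronger selection at equal displacement
  expect_equal(gaussian_fitness(0.95 - 0.2, red), exp(-0.04 / 0.015))
  expect_lt(gaussian_fitness(0.95 - 0.2, red), gaussian_fitness(0.05 + 0.2, blue))
  expect_error(fitness_env(0.5, 0), "variance")
})

test_that("pool evolution keeps a valid genealogy and plausible richness", {
  pool <- evolve_pool(small_pool_params(), seed = 42)
  expect_gt(pool$richness, 100)
  tr <- pool$phylo
  expect_s3_class(tr, "phylo")
  expect_true(ape::is.rooted(tr))
  expect_equal(length(tr$tip.label), pool$richness)
  expect_setequal(tr$tip.label, pool$taxon_ids)
  expect_true(all(tr$edge.length >= 0))
  # every non-root node has exactly one parent edge
  expect_equal(nrow(tr$edge), length(tr$tip.label) + tr$Nnode - 1L)
  # extant tips are contemporaneous (ultrametric genealogy)
  depths <- ape::node.depth.edgelength(tr)[seq_along(tr$tip.label)]
  expect_lt(diff(range(depths)), 1e-8)
  # optima bounded by the reflecting niche axis
  expect_true(all(pool$optima >= 0 & pool$optima <= 1))
  # richness trajectory recorded every step, never zero
  expect_length(pool$richness_trajectory, pool$params$n_steps)
  expect_true(all(pool$richness_trajectory >= 1))
  expect_equal(pool$richness_trajectory[pool$params$n_steps], pool$richness)
  # same seed, same pool
  pool2 <- evolve_pool(small_pool_params(), seed = 42)
  expect_identical(pool$species, pool2$species)
})

test_that("optimum reflection folds values into [0, 1] preserving step size", {
  expect_equal(reflect01(c(0.3, -0.3, 1.2, 2.3, -1.1)),
               c(0.3, 0.3, 0.8, 0.3, 0.9))
})

test_that("community assembly conserves richness and abundance exactly", {
  pool <- evolve_pool(small_pool_params(), seed = 7)
  for (env in list(blue_environment(), red_environment())) {
    v <- assemble_community(pool, env, seed = 1)
    expect_equal(sum(v > 0), 100)
    expect_equal(sum(v), 10000)
  }
  # a zero dispersal coefficient reduces exactly to fitness-only assembly
  c1 <- assemble_community(pool, blue_environment(), seed = 2)
  a <- assemble_community(pool, blue_environment(), seed = 3,
                          source = c1, dispersal_coef = 0)
  b <- assemble_community(pool, blue_environment(), seed = 3)
  expect_identical(a, b)
  expect_error(assemble_community(pool, blue_environment(), n_species = 1e6),
               "pool has")
})

test_that("a larger dispersal exponent couples the community more tightly to its source", {
  pool <- evolve_pool(small_pool_params(), seed = 11)
  set.seed(99)
  bc <- replicate(25, {
    c1 <- assemble_community(pool, blue_environment())
    high <- assemble_community(pool, blue_environment(), source = c1,
                               dispersal_exponent = 1.1)
    low <- assemble_community(pool, blue_environment(), source = c1,
                              dispersal_exponent = 0.8)
    c(high = bray_curtis(c1, high), low = bray_curtis(c1, low))
  })
  expect_lt(mean(bc["high", ]), mean(bc["low", ]))
})

test_that("scenario assembly produces the seven-community benchmark set", {
  pool <- evolve_pool(small_pool_params(), seed = 5)
  comm <- assemble_scenarios(pool, seed = 2)
  expect_equal(rownames(comm), paste0("C", 1:7))
  expect_equal(unname(rowSums(comm)), rep(10000, 7))
  expect_equal(unname(rowSums(comm > 0)), rep(100, 7))
  # dispersal-coupled communities share more of community 1 than decoupled
  shared <- function(s) sum(comm["C1", ] > 0 & comm[s, ] > 0)
  expect_gt(shared("C2"), shared("C4"))
})

test_that("evolved niche optima carry significant phylogenetic signal", {
  pool <- evolve_pool(small_pool_params(), seed = 13)
  sig <- phylogenetic_signal(pool, n_perm = 199, seed = 1)
  expect_gt(sig$statistic, 0)
  expect_lt(sig$p_value, 0.05)
  # permuting optima across tips destroys the signal in most draws
  set.seed(2)
  p_perm <- replicate(10, {
    shuffled <- pool
    shuffled$optima <- setNames(sample(pool$optima), names(pool$optima))
    phylogenetic_signal(shuffled, n_perm = 99)$p_value
  })
  expect_gt(median(p_perm), 0.05)
  # two clades with distinct optima: association near its maximum
  tr <- read_phylogeny(paste0("((", paste0("a", 1:6, ":1", collapse = ","),
                              "):9,(", paste0("b", 1:6, ":1", collapse = ","),
                              "):9);"))
  fake <- list(phylo = tr,
               optima = setNames(c(rep(0.1, 6), rep(0.9, 6)), tr$tip.label))
  sig2 <- phylogenetic_signal(fake, n_perm = 199, seed = 3)
  expect_gt(sig2$statistic, 0.95)
  # degenerate optima rejected
  fake$optima[] <- 0.5
  expect_error(phylogenetic_signal(fake), "degenerate")
})

test_that("validation harness rows are well-formed fractions", {
  pool <- evolve_pool(small_pool_params(), seed = 21)
  vm <- run_validation(pool, n_iter = 3, n_null = 49, seed = 4)
  expect_equal(nrow(vm), 6)
  expect_equal(vm$fraction_primary + vm$fraction_secondary +
                 vm$fraction_unexpected, rep(1, 6), tolerance = 1e-12)
  expect_equal(vm$n, c(3, 3, 3, 3, 6, 3))
  # deterministic under a fixed seed
  vm2 <- run_validation(pool, n_iter = 3, n_null = 49, seed = 4)
  expect_identical(vm, vm2)
})

test_that("fixtures round-trip and cross-environment pairs read as variable selection", {
  dir <- withr::local_tempdir()
  paths <- make_fixture(dir, params = small_pool_params(), n_replicates = 1,
                        seed = 9)
  comm <- read_community_table(paths[["community"]], "taxa_rows")
  tree <- read_phylogeny(paths[["tree"]])
  meta <- read_sample_metadata(paths[["metadata"]])
  rep <- validate_inputs(comm, tree, meta)
  expect_true(rep$phylo_ok && rep$spatial_ok)

  # identical files from the same seed
  dir2 <- withr::local_tempdir()
  paths2 <- make_fixture(dir2, params = small_pool_params(), n_replicates = 1,
                         seed = 9)
  for (k in names(paths))
    expect_identical(readLines(paths[[k]]), readLines(paths2[[k]]))

  # blue-vs-red sample pairs are dominated by variable selection
  res <- run_inference(comm, tree, n_null = 99, seed = 17)
  cross <- with(res$pairs,
    xor(sample_a %in% c("C6_r1", "C7_r1"),
        sample_b %in% c("C6_r1", "C7_r1")))
  calls <- as.character(res$pairs$category[cross])
  expect_gt(mean(calls == "variable_selection"), 0.5)
})
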