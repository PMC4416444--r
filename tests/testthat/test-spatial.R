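test_that("spatial eigenvectors are centered, orthogonal, and match a direct eigen oracle", {
  set.seed(4)
  coords <- cbind(x = runif(9, 0, 10), y = runif(9, 0, 10))
  basis <- pcnm_axes(coords)
  v <- basis$vectors
  expect_true(all(abs(colSums(v)) < 1e-8))
  gram <- crossprod(v)
  expect_equal(gram, diag(basis$values[seq_len(ncol(v))], ncol(v)),
               tolerance = 1e-8, ignore_attr = TRUE)
  # eigenvalues and axes (up to sign) match the brute-force decomposition
  ora <- pcnm_oracle(coords)
  expect_equal(basis$values, ora$values[seq_along(basis$values)],
               tolerance = 1e-8)
  for (k in seq_len(ncol(v))) {
    agree <- min(sum((v[, k] - ora$vectors[, k])^2),
                 sum((v[, k] + ora$vectors[, k])^2))
    expect_lt(agree, 1e-12)
  }
})

test_that("a linear transect yields a first axis ordered along the line", {
  coords <- cbind(x = 0:3, y = rep(0, 4))
  basis <- pcnm_axes(coords)
  a1 <- basis$vectors[, 1]
  expect_true(all(diff(a1) > 0) || all(diff(a1) < 0))
  expect_warning(pcnm_axes(rbind(coords, c(0, 0))), "duplicate")
})

test_that("priority filtering keeps the higher-priority member of correlated pairs", {
  set.seed(10)
  n <- 60
  X <- data.frame(e1 = rnorm(n))
  X$e2 <- X$e1                     # exact duplicate, lower |cor| rank decides
  X$e3 <- rnorm(n)
  y <- X$e1 + rnorm(n, 0, 0.1)
  kept <- priority_filter(X, y, env_vars = c("e1", "e2", "e3"))
  expect_true("e1" %in% kept)
  expect_false("e2" %in% kept)
  expect_true("e3" %in% kept)

  # environmental features outrank spatial axes when they covary
  X$s1 <- X$e3 + rnorm(n, 0, 0.05)
  kept <- priority_filter(X, y, env_vars = c("e1", "e3"), spatial_vars = "s1")
  expect_true(all(c("e1", "e3") %in% kept))
  expect_false("s1" %in% kept)

  # mutually independent candidates are essentially all retained
  set.seed(11)
  Xi <- as.data.frame(matrix(rnorm(400 * 6), 400, 6))
  kept <- priority_filter(Xi, rnorm(400), env_vars = colnames(Xi))
  expect_gte(length(kept), 5)

  expect_warning(
    priority_filter(cbind(X, cz = 1), y, env_vars = c("e1", "cz")),
    "zero-variance")
})

test_that("AICc model selection matches the closed form and recovers noiseless models", {
  # closed form at n = 20, RSS = 10, two predictors (k = 4)
  expect_equal(aicc_ols(n = 20, rss = 10, n_predictors = 2),
               20 * log(10 / 20) + 2 * 4 + 2 * 4 * 5 / (20 - 4 - 1),
               tolerance = 1e-12)
  # correction vanishes for large n
  expect_lt(abs(aicc_ols(1e5, 1, 2) - (1e5 * log(1 / 1e5) + 2 * 4)), 1e-3)

  set.seed(12)
  X <- as.data.frame(matrix(rnorm(30 * 6), 30, 6))
  colnames(X) <- paste0("v", 1:6)
  y <- 2 + 1.5 * X$v2 - 0.8 * X$v5
  model <- best_subsets_aicc(X, y, max_vars = 7)
  expect_setequal(model$variables, c("v2", "v5"))
  expect_equal(model$r_squared, 1, tolerance = 1e-10)
  expect_equal(unname(model$coefficients), c(2, 1.5, -0.8), tolerance = 1e-8)
  # the dominant variable has the largest absolute standardized coefficient
  expect_equal(names(which.max(abs(model$std_coefficients))), "v2")
  expect_error(best_subsets_aicc(as.data.frame(matrix(rnorm(30 * 21), 30)),
                                 rnorm(30)), "20 candidate")
})

test_that("prediction reproduces fitted values, clips fractions, and flags gaps", {
  set.seed(13)
  X <- data.frame(a = rnorm(25), b = rnorm(25))
  y <- 0.4 + 0.3 * X$a + rnorm(25, 0, 0.02)
  model <- best_subsets_aicc(X, y, max_vars = 2)
  pred <- predict_map(model, X, clip = FALSE)
  mm <- cbind(1, as.matrix(X[, model$variables, drop = FALSE]))
  expect_equal(as.numeric(pred), unname(drop(mm %*% model$coefficients)),
               tolerance = 1e-12)
  # clipping marks out-of-range fraction predictions
  far <- data.frame(a = c(0, 100, -100), b = 0)
  clipped <- predict_map(model, far)
  expect_true(all(clipped >= 0 & clipped <= 1))
  expect_equal(attr(clipped, "clipped"), c(FALSE, TRUE, TRUE))
  expect_error(predict_map(model, data.frame(b = 1)), "missing feature")
})

test_that("grid interpolation is exact for data points and linear surfaces", {
  pts <- rbind(c(0, 0), c(1, 0), c(0, 1), c(1, 1), c(0.5, 0.5))
  vals <- 2 + 3 * pts[, 1] - 1.5 * pts[, 2]
  g <- interpolate_grid(pts, vals, resolution = 3)  # nodes at 0, .5, 1
  # node coincident with each data point reproduces its value
  for (i in seq_len(nrow(pts))) {
    hit <- g$x == pts[i, 1] & g$y == pts[i, 2]
    expect_equal(g$value[hit], vals[i], tolerance = 1e-8)
  }
  # a globally linear surface is reproduced at every in-hull node
  g2 <- interpolate_grid(pts, vals, resolution = 9)
  inh <- g2$in_hull
  expect_equal(g2$value[inh], 2 + 3 * g2$x[inh] - 1.5 * g2$y[inh],
               tolerance = 1e-8)
  # barycentric value at the centroid of a triangle
  tri <- rbind(c(0, 0), c(1, 0), c(0, 1))
  g3 <- interpolate_grid(tri, c(0, 0, 3), resolution = 4)  # node at 1/3, 1/3
  ctr <- abs(g3$x - 1 / 3) < 1e-9 & abs(g3$y - 1 / 3) < 1e-9
  expect_equal(g3$value[ctr], 1.0, tolerance = 1e-8)
  # nodes outside the hull are masked
  expect_true(any(!g3$in_hull))
  expect_true(all(is.na(g3$value[!g3$in_hull])))
  expect_error(interpolate_grid(cbind(0:3, 0), 1:4), "collinear")
})

test_that("the full mapping stage recovers a planted linear landscape", {
  set.seed(14)
  n <- 30
  meta <- data.frame(sample_id = paste0("L", 1:n),
                     x = runif(n, 0, 50), y = runif(n, 0, 50),
                     env1 = rnorm(n), env2 = rnorm(n), env3 = rnorm(n))
  fr <- data.frame(sample_id = meta$sample_id,
                   variable_selection = pmin(1, pmax(0,
                     0.4 + 0.2 * meta$env1 + rnorm(n, 0, 0.02))))
  out <- map_process_influence(fr, meta, "variable_selection",
                               env_vars = c("env1", "env2", "env3"),
                               resolution = 20)
  expect_true("env1" %in% out$model$variables)
  expect_equal(names(which.max(abs(out$model$std_coefficients))), "env1")
  # predictions at training locations equal the model's fitted values there
  expect_equal(out$predictions$value,
               as.numeric(predict_map(out$model,
                 cbind(meta, as.data.frame(pcnm_axes(meta)$vectors)))),
               tolerance = 1e-10)
  expect_s3_class(out$grid, "grid_prediction")
})
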